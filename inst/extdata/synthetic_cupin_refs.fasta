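>synthetic_cupin_ref_1 synthetic stand-in for a cupin-domain reference (random sequence, fixed seed)
HGGIASNQAWMTCSSIDQRGKWYDDGFCPMFMYRIFHIIAYNTVYQYPLAWFDCWPECYH
WTSLKMIDTMCEHEMVTDMEFDTTLDLNMQPCVHITGITHFPDVAVGHFI
>synthetic_cupin_ref_2 synthetic stand-in for a cupin-domain reference (random sequence, fixed seed)
HLQSPPGGLWYMDVIFVHDAMAQTQLFVWPSSWLLLGHYNQQHHGSRKTKYGMCFNQCNK
TFMPQCKDTIGPNKFKWDECKMIFIQACPPGAQWTGLKVDVGLVRKRYIK
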