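site	k_m_nM	v_max_nM_min	specificity_direct_min	reference
-GAATTCG-/-CTTAAGC-	20.0	0.30	NA	TRUE
-XAATTCG-/-CTTAAGC-	NA	NA	NA	FALSE
-GAATTCG-/-CTTAAXC-	NA	NA	0.00031	FALSE
-GAATTCX-/-CTTAAGC-	40.0	0.067	NA	FALSE
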