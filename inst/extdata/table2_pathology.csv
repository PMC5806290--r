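case_id,glomeruli,cell_proliferation,leucocyte_exudation,karyorrhexis_necrosis,cellular_crescents,hyaline_deposits,interstitial_inflammation,ai_total,glomerular_sclerosis,fibrous_crescents,tubular_atrophy,interstitial_fibrosis,ci_total,diagnosis
1,14,2,1,1,2,1,2,9,1,0,1,1,3,IV-G (A/C) + V
2,28,2,2,2,1,2,2,11,1,0,1,1,3,IV-G (A/C) + V
3,41,2,1,1,3,2,1,10,0,0,1,1,2,IV-G (A/C)
4,16,2,2,0,2,2,1,9,0,0,1,1,2,IV-G (A/C) + V
5,21,1,2,1,1,2,1,8,0,0,1,1,2,III-(A/C) + V
6,16,1,1,0,0,1,1,4,0,0,1,1,2,III-(A/C) + V
7,17,1,2,0,1,1,1,6,0,0,1,1,2,III-(A/C) + V
8,27,1,2,1,1,1,1,7,1,0,1,1,3,III-(A/C)
9,21,1,0,0,1,1,1,4,0,0,1,1,2,III-(A/C)
10,15,2,1,0,3,1,1,8,0,0,1,1,2,IV-G (A/C)
11,15,2,1,1,1,2,2,9,0,0,2,1,3,IV-G (A/C)
12,21,2,1,2,2,2,2,11,0,0,1,1,2,IV-G (A/C) + V
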