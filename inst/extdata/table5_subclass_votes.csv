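case_id,diagnosis,primary_votes_III,primary_votes_IV,votes_homogeneity,votes_heterogeneity
1,IV-G (A/C) + V,74,226,50,250
2,IV-G (A/C) + V,125,175,16,284
3,IV-G (A/C),119,181,104,196
4,IV-G (A/C) + V,103,197,89,211
5,III-(A/C) + V,166,137,61,239
6,III-(A/C) + V,180,120,19,281
7,III-(A/C) + V,221,79,39,261
8,III-(A/C),218,82,179,121
9,III-(A/C),173,127,280,20
10,IV-G (A/C),70,230,192,108
11,IV-G (A/C),67,238,279,21
12,IV-G (A/C) + V,34,266,58,242
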