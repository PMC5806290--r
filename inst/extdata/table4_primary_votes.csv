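case_id,model,votes_III,votes_IV
1,decision_tree,74,226
2,decision_tree,125,175
3,decision_tree,119,181
4,decision_tree,103,197
5,decision_tree,166,134
6,decision_tree,180,120
7,decision_tree,221,79
8,decision_tree,218,82
9,decision_tree,173,127
10,decision_tree,70,230
11,decision_tree,67,233
12,decision_tree,34,266
1,line_discriminant,44,256
2,line_discriminant,263,37
3,line_discriminant,186,114
4,line_discriminant,188,112
5,line_discriminant,195,105
6,line_discriminant,243,57
7,line_discriminant,263,37
8,line_discriminant,194,106
9,line_discriminant,61,239
10,line_discriminant,133,167
11,line_discriminant,4,296
12,line_discriminant,33,267
1,logistic,8,292
2,logistic,176,124
3,logistic,95,205
4,logistic,113,187
5,logistic,112,188
6,logistic,164,136
7,logistic,209,91
8,logistic,71,229
9,logistic,14,286
10,logistic,50,250
11,logistic,1,299
12,logistic,4,296
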