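"file","md5"
"table1_clinical.csv","0b9d5f9844f319a5ae8f16567271e55b"
"table2_pathology.csv","dfa4f62dda47125f04234e32316cd4a7"
"table4_primary_votes.csv","e68b769a4a2a63092d25d2ccd0615269"
"table5_subclass_votes.csv","3eda49f06b699f8678e2d7947a020394"
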