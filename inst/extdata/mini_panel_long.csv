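household_id,wave,item,level_code
h1,1983,radio,0
h1,1983,tv,0
h1,1983,roof,1
h1,1991,radio,1
h1,1991,tv,0
h1,1991,roof,1
h2,1983,radio,1
h2,1983,tv,0
h2,1983,roof,0
h2,1991,radio,1
h2,1991,tv,1
h2,1991,roof,2
h3,1983,radio,0
h3,1983,tv,1
h3,1983,roof,2
h3,1991,radio,1
h3,1991,tv,1
h3,1991,roof,2
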