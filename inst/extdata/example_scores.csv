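"group","f1","f2","f3","f4","f5","f6","f7","f8","f9","f10"
"0",0,1,1,0,0,0,0,1,1,0
"0",0,0,0,1,0,0,1,1,0,0
"0",0,1,1,0,0,1,0,0,0,1
"0",1,0,1,0,1,0,1,0,0,0
"0",0,0,1,0,1,0,1,1,0,1
"0",1,0,0,0,0,0,0,1,0,0
"0",1,0,0,0,0,0,1,1,0,1
"0",1,0,1,1,0,1,0,1,0,0
"0",1,1,1,0,1,1,0,0,1,0
"0",0,1,1,0,0,1,1,0,1,0
"33",0,1,1,0,0,1,1,0,0,0
"33",0,1,1,1,0,0,0,0,0,1
"33",1,0,0,1,0,0,1,1,0,1
"33",0,0,0,0,1,0,0,1,0,1
"33",1,1,1,0,0,0,0,0,0,0
"33",0,1,0,1,0,1,1,1,0,1
"33",1,1,1,1,1,1,1,1,0,0
"33",1,0,0,0,0,0,1,1,1,1
"33",0,0,1,0,1,0,0,0,0,1
"33",1,1,1,0,0,1,0,0,0,0
"66",1,1,1,0,1,0,0,1,1,0
"66",0,0,0,0,0,0,1,0,0,1
"66",1,0,1,0,1,0,1,1,0,0
"66",0,0,0,0,0,1,1,0,0,1
"66",0,1,0,0,0,0,1,0,1,1
"66",0,0,1,0,0,0,1,0,0,1
"66",0,1,0,0,1,0,1,1,1,1
"66",0,1,0,1,0,1,0,0,0,0
"66",1,0,0,0,0,0,0,0,1,1
"66",0,0,1,0,1,0,0,0,1,0
"66",0,0,0,1,0,1,0,1,1,1
"66",0,0,1,0,1,0,0,0,1,0
"66",0,1,0,0,1,0,0,1,1,0
"166",0,0,0,0,0,0,0,0,0,0
"166",1,0,0,0,0,0,0,0,0,0
"166",1,1,0,0,0,1,1,0,0,0
"166",1,1,0,0,1,0,0,0,1,1
"166",0,0,0,0,0,1,1,1,1,0
"166",1,0,0,0,0,1,1,0,1,0
"166",0,0,0,0,0,0,0,1,0,1
"166",1,1,0,1,0,0,0,0,0,0
"166",1,0,1,0,1,0,0,1,1,0
"166",1,0,1,0,0,0,1,1,0,1
"166",0,0,0,1,0,0,0,0,0,0
"166",0,0,1,0,0,0,0,0,0,1
"166",1,0,1,0,0,1,1,1,0,0
"166",0,0,1,0,1,1,1,0,0,1
"166",0,0,0,1,1,0,0,0,1,1
"166",1,0,1,1,0,0,0,0,0,0
"166",1,1,1,0,0,1,1,0,1,1
"166",0,1,1,0,1,0,1,1,1,0
"166",1,0,0,0,1,1,0,1,1,1
"166",0,0,0,0,0,1,0,1,0,0
"166",0,0,0,1,1,0,0,0,1,0
"166",0,1,0,0,0,0,1,1,0,0
"166",0,0,0,1,0,0,1,0,0,0
"166",0,1,1,0,1,1,1,1,0,0
"333",0,1,0,0,0,0,0,0,0,1
"333",1,0,0,0,0,0,0,0,1,0
"333",0,0,0,0,0,1,1,1,0,0
"333",1,1,0,1,1,1,1,1,1,1
"333",0,0,1,1,0,0,1,1,0,1
"333",0,0,0,0,0,1,0,1,1,0
"333",0,1,0,0,0,1,1,1,0,1
"333",1,0,0,0,1,0,0,0,0,0
"333",0,1,1,0,0,0,1,0,1,0
"333",0,1,0,1,1,0,0,0,0,1
"333",1,0,1,1,1,0,0,0,0,1
"333",0,0,1,1,1,1,0,0,0,1
"333",1,0,0,0,1,0,0,0,0,0
"333",0,0,0,0,0,0,1,1,1,0
"333",1,0,0,1,1,1,0,1,0,0
"333",0,0,0,1,0,0,1,0,0,0
"333",0,0,0,1,1,0,0,1,0,1
"1000",0,0,1,1,1,0,1,0,0,1
"1000",1,0,0,1,0,0,1,1,1,1
"1000",1,0,0,0,1,0,0,0,0,1
"1000",0,1,0,1,1,0,1,0,1,1
"1000",1,0,0,1,1,1,1,1,0,0
"1000",1,1,0,0,0,0,0,0,1,0
"1000",0,1,0,0,0,0,0,0,0,0
"1000",1,0,1,1,0,1,0,1,0,1
"1000",0,0,1,0,1,1,0,1,0,1
"1000",0,0,1,0,1,1,0,0,0,0
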