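endpoint,component,arm,arm_n,count,printed_pct
first,overall,GLY,1859,1117,60.1
first,overall,TIO,1077,622,57.8
first,FEV1,GLY,1859,715,38.5
first,FEV1,TIO,1077,404,37.5
first,SGRQ,GLY,1859,432,23.2
first,SGRQ,TIO,1077,249,23.1
first,EXACERBATION,GLY,1859,390,21.0
first,EXACERBATION,TIO,1077,194,18.0
sustained,overall,GLY,1859,996,53.6
sustained,overall,TIO,1077,541,50.2
sustained,FEV1,GLY,1859,531,28.6
sustained,FEV1,TIO,1077,296,27.5
sustained,SGRQ,GLY,1859,104,5.6
sustained,SGRQ,TIO,1077,64,5.9
sustained,EXACERBATION,GLY,1859,390,21.0
sustained,EXACERBATION,TIO,1077,194,18.0
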