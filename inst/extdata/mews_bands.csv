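parameter,lo,hi,points
sbp,-Inf,71,3
sbp,71,81,2
sbp,81,101,1
sbp,101,200,0
sbp,200,Inf,2
hr,-Inf,41,2
hr,41,51,1
hr,51,101,0
hr,101,111,1
hr,111,130,2
hr,130,Inf,3
rr,-Inf,9,2
rr,9,15,0
rr,15,21,1
rr,21,30,2
rr,30,Inf,3
temp,-Inf,35,2
temp,35,38.5,0
temp,38.5,Inf,2
avpu,0,1,0
avpu,1,2,1
avpu,2,3,2
avpu,3,4,3
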