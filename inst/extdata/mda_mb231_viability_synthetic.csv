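agent_a,dose_a,agent_b,dose_b,replicate,response,response_kind
control,0,,0,1,98,percent_viability
control,0,,0,2,98,percent_viability
control,0,,0,3,98,percent_viability
Q,10,,0,1,87,percent_viability
Q,10,,0,2,87,percent_viability
Q,10,,0,3,87,percent_viability
Q,20,,0,1,82,percent_viability
Q,20,,0,2,82,percent_viability
Q,20,,0,3,82,percent_viability
Q,40,,0,1,76,percent_viability
Q,40,,0,2,76,percent_viability
Q,40,,0,3,76,percent_viability
Q,80,,0,1,56,percent_viability
Q,80,,0,2,56,percent_viability
Q,80,,0,3,56,percent_viability
Q,100,,0,1,42,percent_viability
Q,100,,0,2,42,percent_viability
Q,100,,0,3,42,percent_viability
GEM,1,,0,1,78,percent_viability
GEM,1,,0,2,78,percent_viability
GEM,1,,0,3,78,percent_viability
GEM,2,,0,1,66,percent_viability
GEM,2,,0,2,66,percent_viability
GEM,2,,0,3,66,percent_viability
GEM,4,,0,1,58,percent_viability
GEM,4,,0,2,58,percent_viability
GEM,4,,0,3,58,percent_viability
GEM,8,,0,1,46,percent_viability
GEM,8,,0,2,46,percent_viability
GEM,8,,0,3,46,percent_viability
GEM,10,,0,1,28,percent_viability
GEM,10,,0,2,28,percent_viability
GEM,10,,0,3,28,percent_viability
Q,10,GEM,1,1,64,percent_viability
Q,10,GEM,1,2,64,percent_viability
Q,10,GEM,1,3,64,percent_viability
Q,20,GEM,2,1,48,percent_viability
Q,20,GEM,2,2,48,percent_viability
Q,20,GEM,2,3,48,percent_viability
Q,40,GEM,4,1,30,percent_viability
Q,40,GEM,4,2,30,percent_viability
Q,40,GEM,4,3,30,percent_viability
Q,80,GEM,8,1,38,percent_viability
Q,80,GEM,8,2,38,percent_viability
Q,80,GEM,8,3,38,percent_viability
Q,100,GEM,10,1,24,percent_viability
Q,100,GEM,10,2,24,percent_viability
Q,100,GEM,10,3,24,percent_viability
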