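marker,units,group,replicate,value
ROS,fold_of_control,control,1,1.0
ROS,fold_of_control,Q,1,1.6
ROS,fold_of_control,GEM,1,2.4
ROS,fold_of_control,Q_GEM,1,2.8
caspase3,fold_of_control,control,1,1.0
caspase3,fold_of_control,Q,1,2.1
caspase3,fold_of_control,GEM,1,3.0
caspase3,fold_of_control,Q_GEM,1,3.6
apoptosis,percent_cells,control,1,2.8
apoptosis,percent_cells,Q,1,24.6
apoptosis,percent_cells,GEM,1,38.4
apoptosis,percent_cells,Q_GEM,1,44.2
SOD,percent_of_control,control,1,100
SOD,percent_of_control,Q,1,125
SOD,percent_of_control,GEM,1,110
CAT,percent_of_control,control,1,100
CAT,percent_of_control,Q,1,120
GSH,percent_of_control,control,1,100
GSH,percent_of_control,Q,1,90
GSH,percent_of_control,GEM,1,75
GSH,percent_of_control,Q_GEM,1,60
MDA,percent_of_control,control,1,100
MDA,percent_of_control,Q,1,140
MDA,percent_of_control,GEM,1,180
MDA,percent_of_control,Q_GEM,1,220
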