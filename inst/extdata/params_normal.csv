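# gravicor compartment parameter table (calibrated healthy baseline)
# E, emin, emax: elastance, mmHg/mL | vu, dvu_0g: mL
# height: hydrostatic column, cm, signed positive above heart level
# thoracic/atrial/vu_ctl/emax_ctl: logical flags
name,group,kind,E,emin,emax,vu,height,thoracic,atrial,dvu_0g,vu_ctl,emax_ctl
ra,cardiac,cardiac,NA,0.2,0.35,25,0,TRUE,TRUE,0,FALSE,FALSE
rv,cardiac,cardiac,NA,0.062,1.1,18,0,TRUE,FALSE,0,FALSE,TRUE
la,cardiac,cardiac,NA,1.8,2.3,32.1,0,TRUE,TRUE,0,FALSE,FALSE
lv,cardiac,cardiac,NA,0.1,2.5,14,0,TRUE,FALSE,0,FALSE,TRUE
ao_th,intrathoracic,vascular,1.95,NA,NA,120,0,TRUE,FALSE,0,FALSE,FALSE
pa,intrathoracic,vascular,0.45,NA,NA,110,0,TRUE,FALSE,0,FALSE,FALSE
pv,intrathoracic,vascular,0.08,NA,NA,400,0,TRUE,FALSE,-310,FALSE,FALSE
svc,intrathoracic,vascular,0.3,NA,NA,95,12,TRUE,FALSE,0,FALSE,FALSE
ivc_th,intrathoracic,vascular,0.25,NA,NA,122,-4,TRUE,FALSE,0,FALSE,FALSE
ub_art,upper_body,vascular,2.5,NA,NA,100,25,FALSE,FALSE,0,FALSE,FALSE
ub_vein,upper_body,vascular,0.055,NA,NA,450,25,FALSE,FALSE,0,TRUE,FALSE
ao_ab,lower_body,vascular,2,NA,NA,80,-15,FALSE,FALSE,0,FALSE,FALSE
ren_art,lower_body,vascular,5,NA,NA,30,-20,FALSE,FALSE,0,FALSE,FALSE
ren_vein,lower_body,vascular,0.3,NA,NA,120,-20,FALSE,FALSE,0,TRUE,FALSE
spl_art,lower_body,vascular,4,NA,NA,60,-12,FALSE,FALSE,0,FALSE,FALSE
spl_vein,lower_body,vascular,0.024,NA,NA,1250,-8,FALSE,FALSE,-10,TRUE,FALSE
pel_art,lower_body,vascular,4.4,NA,NA,40,-35,FALSE,FALSE,0,FALSE,FALSE
pel_vein,lower_body,vascular,0.25,NA,NA,220,-35,FALSE,FALSE,-10,TRUE,FALSE
leg_art,lower_body,vascular,3.2,NA,NA,90,-60,FALSE,FALSE,0,FALSE,FALSE
leg_vein,lower_body,vascular,0.25,NA,NA,450,-60,FALSE,FALSE,-20,TRUE,FALSE
ivc_ab,lower_body,vascular,0.14,NA,NA,230,-18,FALSE,FALSE,-5,TRUE,FALSE
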