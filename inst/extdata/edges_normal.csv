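# gravicor edge list | R: mmHg s/mL
# valved: ideal diode | r_ctl: reflex resistance effector
from,to,R,valved,r_ctl
lv,ao_th,0.006,TRUE,FALSE
ao_th,ub_art,0.12,FALSE,FALSE
ao_th,ao_ab,0.06,FALSE,FALSE
ub_art,ub_vein,4.03,FALSE,TRUE
ub_vein,svc,0.06,FALSE,FALSE
svc,ra,0.015,FALSE,FALSE
ao_ab,ren_art,0.05,FALSE,FALSE
ao_ab,spl_art,0.05,FALSE,FALSE
ao_ab,pel_art,0.05,FALSE,FALSE
pel_art,leg_art,0.06,FALSE,FALSE
ren_art,ren_vein,4.56,FALSE,TRUE
spl_art,spl_vein,3.1,FALSE,TRUE
pel_art,pel_vein,11,FALSE,TRUE
leg_art,leg_vein,9.1,FALSE,TRUE
ren_vein,ivc_ab,0.06,FALSE,FALSE
spl_vein,ivc_ab,0.05,FALSE,FALSE
pel_vein,ivc_ab,0.06,FALSE,FALSE
leg_vein,pel_vein,0.07,FALSE,FALSE
ivc_ab,ivc_th,0.025,FALSE,FALSE
ivc_th,ra,0.01,FALSE,FALSE
ra,rv,0.004,TRUE,FALSE
rv,pa,0.005,TRUE,FALSE
pa,pv,0.045,FALSE,FALSE
pv,la,0.008,FALSE,FALSE
la,lv,0.021,TRUE,FALSE
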