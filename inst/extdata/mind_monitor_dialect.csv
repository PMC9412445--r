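path,field,mandatory
/muse/elements/delta_absolute,delta,1
/muse/elements/theta_absolute,theta,1
/muse/elements/alpha_absolute,alpha,1
/muse/elements/beta_absolute,beta,1
/muse/elements/gamma_absolute,gamma,1
/muse/elements/horseshoe,fit,0
/muse/batt,battery,0
/muse/gyro,gyroscope,0
/muse/acc,accelerometer,0
/muse/elements/blink,blink,0
/muse/elements/jaw_clench,jaw_clench,0
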