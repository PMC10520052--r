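chemical,matrix,mean,sd,min,max,n_refs,mean_printed,sd_printed,min_printed,max_printed,n_refs_printed
formaldehyde,e-liquid,5.41e-3,2.08e-2,0,1.97e-1,7,5.41e-3,2.08e-2,0,1.97e-1,7
acetaldehyde,e-liquid,3.03e-3,5.68e-3,0,4.29e-2,2,3.03e-3,5.68e-3,0,4.29e-2,2
acetone,e-liquid,8.61e-5,2.16e-4,0,1e-3,2,8.61e-5,2.16e-4,0,1e-3,2
acrolein,e-liquid,3.06e-2,7.04e-2,0,3.27e-1,2,3.06e-2,7.04e-2,0,3.27e-1,2
As,e-liquid,2.72e-5,9.27e-5,0,4.30e-4,4,2.72e-5,9.27e-5,0,4.30e-4,4
Cd,e-liquid,7.58e-5,5.93e-5,1e-8,2.20e-4,6,7.58e-5,5.93e-5,1e-8,2.20e-4,6
Mn,e-liquid,6.35e-4,1.79e-3,0,6.91e-3,4,6.35e-4,1.79e-3,0,6.91e-3,4
Pb,e-liquid,5.25e-4,1.88e-3,0,1.35e-2,7,5.25e-4,1.88e-3,0,1.35e-2,7
Cu,e-liquid,1.05e-1,2.41e-1,0,9.27e-1,5,1.05e-1,2.41e-1,0,9.27e-1,5
Ni,e-liquid,3.93e-3,1.10e-2,0,6.13e-2,6,3.93e-3,1.10e-2,0,6.13e-2,6
Cr,e-liquid,1.34e-4,3.29e-4,0,2.11e-3,8,1.34e-4,3.29e-4,0,2.11e-3,8
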