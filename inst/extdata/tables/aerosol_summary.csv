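chemical,matrix,mean,sd,min,max,n_refs,mean_printed,sd_printed,min_printed,max_printed,n_refs_printed
formaldehyde,aerosol,0.864,3.32,0,28.1,12,0.864,3.32,0,28.1,12
acetaldehyde,aerosol,0.673,2.78,0,22.5,12,0.673,2.78,0,22.5,12
acetone,aerosol,0.242,0.396,0,1.66,5,0.373,0.753,0,4.11,7
acrolein,aerosol,0.373,0.753,0,4.11,7,0.242,0.396,0,1.66,5
As,aerosol,2.41e-4,3.79e-4,0,1.74e-3,3,2.41e-4,3.79e-4,0,1.74e-3,3
Cd,aerosol,5.63e-6,1.70e-5,0,1e-4,6,5.63e-6,1.70e-5,0,1e-4,6
Mn,aerosol,6.75e-3,1.08e-2,5e-5,3.21e-2,4,6.75e-3,1.08e-2,5e-5,3.21e-2,4
Pb,aerosol,3.76e-3,2.37e-2,0,2.36e-1,8,3.76e-3,2.37e-2,0,2.36e-1,8
Cu,aerosol,3.47e-2,8.05e-2,2e-5,3.84e-1,6,3.47e-2,8.05e-2,2e-5,3.84e-1,6
Ni,aerosol,1.47e-2,8.99e-2,1.5e-9,7.38e-1,9,1.47e-2,8.99e-2,1.5e-9,7.38e-1,9
Cr,aerosol,3.70e-4,1.48e-3,0,1.58e-2,9,3.70e-4,1.48e-3,0,1.58e-2,9
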