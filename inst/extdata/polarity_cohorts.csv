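cohort_id,marker,soma_contact,spacing_bin,n,pct_on,pm_printed_pct,unclassified_pct,null_p,sig_printed
sprout_dense,first_sprout,interface,0.6-1,31,96.8,3.2,NA,0.5,p<0.05
sprout_intermediate,first_sprout,interface,1.2-2,37,94.6,5.4,NA,0.5,p<0.05
sprout_sparse,first_sprout,interface,2.4-7,18,83.3,16.7,NA,0.5,p<0.05
golgi_dense,golgi,interface,0.6-1,53,69.8,6.3,NA,0.5,p<0.05
golgi_intermediate,golgi,interface,1.2-2,53,64.2,6.6,NA,0.5,p<0.05
golgi_sparse,golgi,interface,2.4-7,43,67.4,7.1,NA,0.5,p<0.05
ncad_cover_dense,ncadherin,covering,0.6-1,112,65.2,4.5,8.9,0.5,p<0.05
ncad_cover_intermediate,ncadherin,covering,1.2-2,115,67.8,4.4,5.7,0.5,p<0.05
ncad_cover_sparse,ncadherin,covering,2.4-7,67,67.2,5.7,5.6,0.5,p<0.05
ncad_touch_dense,ncadherin,touching,0.6-1,68,60.3,5.9,6.8,0.5,p<0.1
ncad_touch_intermediate,ncadherin,touching,1.2-2,58,70.7,6.0,7.9,0.5,p<0.05
ncad_touch_sparse,ncadherin,touching,2.4-7,109,58.7,4.7,9.2,0.5,p<0.1
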