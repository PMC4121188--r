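# mindivsim tracking v1
cell_id,parent_id,birth_t,division_t,birth_length_nm,division_length_nm,division_class,site_appeared_t,n_clusters
1,NA,0,92.5,2411.5,4871.25,nonpolar,75.0,1
2,1,92.5,121.75,2435.625,3187.5,polar_old,92.5,1
2,1,92.5,188.0,2435.625,5910.125,nonpolar,170.5,2
3,1,92.5,201.5,2435.625,6602.75,nonpolar,178.25,2
4,2,188.0,210.0,2955.0625,3590.5,polar_new,188.0,1
5,2,188.0,209.0,2955.0625,3562.875,nonpolar,187.75,1
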