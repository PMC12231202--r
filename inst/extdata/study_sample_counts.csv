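characteristic,category,n
release_site,Duchang,20
release_site,Nanjishan,17
source,capture,30
source,rescue,7
tracker,neck,17
tracker,backpack,20
species,A. fabalis,25
species,A. albifrons,12
release_year,2019,25
release_year,2022,12
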