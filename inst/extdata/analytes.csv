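code,lineage,alkyl_class,ring_class,form,formula,acid_partner,sim_mz
THCA,THC-type,C5,tricyclic,acid,C22H30O4,,359.5
THC,THC-type,C5,tricyclic,neutral,C21H30O2,THCA,315.5
THCVA,THC-type,C3,tricyclic,acid,C20H26O4,,331.4
THCV,THC-type,C3,tricyclic,neutral,C19H26O2,THCVA,287.4
CBDA,CBD-type,C5,dicyclic,acid,C22H30O4,,359.5
CBD,CBD-type,C5,dicyclic,neutral,C21H30O2,CBDA,315.5
CBDVA,CBD-type,C3,dicyclic,acid,C20H26O4,,331.4
CBDV,CBD-type,C3,dicyclic,neutral,C19H26O2,CBDVA,287.4
CBGA,CBG-type,n/a,precursor,acid,C22H32O4,,361.5
CBG,CBG-type,n/a,precursor,neutral,C21H32O2,CBGA,317.5
CBN,CBN-type,n/a,other,neutral,C21H26O2,,311.4
CBC,CBC-type,n/a,other,neutral,C21H30O2,,315.5
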