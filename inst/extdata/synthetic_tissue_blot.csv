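protein,liver,kidney,muscle,brain,heart,lung,spleen,testis,ovary,pancreas,placenta
liver_restricted_a,20020,1040,650,520,580,540,490,560,410,600,590
liver_restricted_b,18200,780,900,680,720,700,610,740,560,650,860
broadly_expressed,3120,2160,2400,1920,2280,2040,1800,2520,1200,2160,2400
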