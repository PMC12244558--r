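rank,group,n_species,order
order,Rotaliida,270,
order,Miliolida,142,
order,Lituolida,32,
order,Textulariida,22,
order,Nodosariida,11,
order,Polymorphinida,11,
order,Spirillinida,2,
order,Astrorhizida,1,
order,Robertinida,1,
genus,Quinqueloculina,69,Miliolida
genus,Triloculina,26,Miliolida
genus,Spiroloculina,22,Miliolida
genus,Elphidium,20,Rotaliida
genus,Ammonia,15,Rotaliida
genus,Bolivina,14,Rotaliida
wall_type,hyaline,288,
wall_type,porcelaneous,142,
wall_type,agglutinated,62,
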