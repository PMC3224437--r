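# fatty-acid pathway model
node C2:0 domain=biosynthesis tags=de_novo
node C4:0 domain=biosynthesis tags=de_novo
node C6:0 domain=biosynthesis tags=de_novo
node C8:0 domain=biosynthesis tags=de_novo
node C10:0 domain=biosynthesis tags=de_novo
node C12:0 domain=biosynthesis tags=de_novo
node C14:0 domain=biosynthesis tags=de_novo
node C16:0 domain=biosynthesis tags=de_novo
node C18:0 domain=biosynthesis tags=de_novo
node C20:0 domain=biosynthesis tags=de_novo
node C22:0 domain=biosynthesis tags=de_novo
node C24:0 domain=biosynthesis tags=de_novo
node C26:0 domain=biosynthesis tags=de_novo
node C16:1 domain=biosynthesis tags=de_novo
node C18:1 domain=biosynthesis tags=de_novo
node C18:2 domain=biosynthesis tags=omega6
node C18:3 domain=biosynthesis tags=omega6,omega3
node C20:3 domain=biosynthesis tags=omega6
node C20:4 domain=biosynthesis tags=omega6,omega3
node C22:4 domain=biosynthesis tags=omega6
node C24:4 domain=biosynthesis tags=omega6
node C24:5 domain=biosynthesis tags=omega6,omega3
node C22:5 domain=biosynthesis tags=omega6,omega3
node C18:4 domain=biosynthesis tags=omega3
node C20:5 domain=biosynthesis tags=omega3
node C24:6 domain=biosynthesis tags=omega3
node C22:6 domain=biosynthesis tags=omega3
node C2:0 domain=beta_oxidation tags=degradation
node C4:0 domain=beta_oxidation tags=degradation
node C6:0 domain=beta_oxidation tags=degradation
node C8:0 domain=beta_oxidation tags=degradation
node C10:0 domain=beta_oxidation tags=degradation
node C12:0 domain=beta_oxidation tags=degradation
node C14:0 domain=beta_oxidation tags=degradation
node C16:0 domain=beta_oxidation tags=degradation
node C18:0 domain=beta_oxidation tags=degradation
node C4:1 domain=beta_oxidation tags=degradation
node C6:1 domain=beta_oxidation tags=degradation
node C8:1 domain=beta_oxidation tags=degradation
node C10:1 domain=beta_oxidation tags=degradation
node C12:1 domain=beta_oxidation tags=degradation
node C14:1 domain=beta_oxidation tags=degradation
node C16:1 domain=beta_oxidation tags=degradation
node C18:1 domain=beta_oxidation tags=degradation
node C6:2 domain=beta_oxidation tags=degradation
node C8:2 domain=beta_oxidation tags=degradation
node C10:2 domain=beta_oxidation tags=degradation
node C12:2 domain=beta_oxidation tags=degradation
node C14:2 domain=beta_oxidation tags=degradation
node C16:2 domain=beta_oxidation tags=degradation
node C18:2 domain=beta_oxidation tags=degradation
edge C2:0 C4:0 type=elongation domain=biosynthesis
edge C4:0 C6:0 type=elongation domain=biosynthesis
edge C6:0 C8:0 type=elongation domain=biosynthesis
edge C8:0 C10:0 type=elongation domain=biosynthesis
edge C10:0 C12:0 type=elongation domain=biosynthesis
edge C12:0 C14:0 type=elongation domain=biosynthesis
edge C14:0 C16:0 type=elongation domain=biosynthesis
edge C16:0 C18:0 type=elongation domain=biosynthesis
edge C18:0 C20:0 type=elongation domain=biosynthesis
edge C20:0 C22:0 type=elongation domain=biosynthesis
edge C22:0 C24:0 type=elongation domain=biosynthesis
edge C24:0 C26:0 type=elongation domain=biosynthesis
edge C16:0 C16:1 type=desaturation domain=biosynthesis
edge C18:0 C18:1 type=desaturation domain=biosynthesis
edge C18:2 C18:3 type=desaturation domain=biosynthesis
edge C18:3 C20:3 type=elongation domain=biosynthesis
edge C20:3 C20:4 type=desaturation domain=biosynthesis
edge C20:4 C22:4 type=elongation domain=biosynthesis
edge C22:4 C24:4 type=elongation domain=biosynthesis
edge C24:4 C24:5 type=desaturation domain=biosynthesis
edge C24:5 C22:5 type=beta_oxidation domain=biosynthesis
edge C18:3 C18:4 type=desaturation domain=biosynthesis
edge C18:4 C20:4 type=elongation domain=biosynthesis
edge C20:4 C20:5 type=desaturation domain=biosynthesis
edge C20:5 C22:5 type=elongation domain=biosynthesis
edge C22:5 C24:5 type=elongation domain=biosynthesis
edge C24:5 C24:6 type=desaturation domain=biosynthesis
edge C24:6 C22:6 type=beta_oxidation domain=biosynthesis
edge C2:0 C4:0 type=beta_oxidation domain=beta_oxidation
edge C4:0 C6:0 type=beta_oxidation domain=beta_oxidation
edge C6:0 C8:0 type=beta_oxidation domain=beta_oxidation
edge C8:0 C10:0 type=beta_oxidation domain=beta_oxidation
edge C10:0 C12:0 type=beta_oxidation domain=beta_oxidation
edge C12:0 C14:0 type=beta_oxidation domain=beta_oxidation
edge C14:0 C16:0 type=beta_oxidation domain=beta_oxidation
edge C16:0 C18:0 type=beta_oxidation domain=beta_oxidation
edge C4:1 C6:1 type=beta_oxidation domain=beta_oxidation
edge C6:1 C8:1 type=beta_oxidation domain=beta_oxidation
edge C8:1 C10:1 type=beta_oxidation domain=beta_oxidation
edge C10:1 C12:1 type=beta_oxidation domain=beta_oxidation
edge C12:1 C14:1 type=beta_oxidation domain=beta_oxidation
edge C14:1 C16:1 type=beta_oxidation domain=beta_oxidation
edge C16:1 C18:1 type=beta_oxidation domain=beta_oxidation
edge C6:2 C8:2 type=beta_oxidation domain=beta_oxidation
edge C8:2 C10:2 type=beta_oxidation domain=beta_oxidation
edge C10:2 C12:2 type=beta_oxidation domain=beta_oxidation
edge C12:2 C14:2 type=beta_oxidation domain=beta_oxidation
edge C14:2 C16:2 type=beta_oxidation domain=beta_oxidation
edge C16:2 C18:2 type=beta_oxidation domain=beta_oxidation
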