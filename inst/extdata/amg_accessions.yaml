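# Auxiliary metabolic gene accession set: KEGG orthologs / PFAM domains
# accepted as AMGs, with the metabolic pathway each one labels.
# Editable; a small illustrative default (nrdA, psbA and friends), not the
# complete curated set.
amgs:
  K00525: {gene: nrdA, pathway: "Purine and pyrimidine metabolism"}
  K02703: {gene: psbA, pathway: "Photosynthesis"}
  K00560: {gene: thyA, pathway: "Pyrimidine metabolism"}
  K01494: {gene: dcd,  pathway: "Pyrimidine metabolism"}
  K00287: {gene: folA, pathway: "Folate biosynthesis"}
  K00963: {gene: galU, pathway: "Amino sugar and nucleotide sugar metabolism"}
  K00067: {gene: rfbD, pathway: "O-antigen nucleotide sugar biosynthesis"}
  K00969: {gene: nadD, pathway: "Nicotinate and nicotinamide metabolism"}
  PF00317: {gene: nrdA, pathway: "Purine and pyrimidine metabolism"}
  PF00124: {gene: psbA, pathway: "Photosynthesis"}
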