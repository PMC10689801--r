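# Anti-viral defence systems: required components and the PFAM accessions
# accepted as conserved-domain confirmation for each component.
# Editable; the shipped set is a small illustrative default, not a complete
# curation of any database.
systems:
  RM:
    components:
      methyltransferase: [PF02384, PF01555, PF13659]
      restriction_endonuclease: [PF04313, PF18766, PF09517]
      specificity_subunit: [PF01420]
  CRISPR-Cas:
    components:
      cas1: [PF01867]
      cas2: [PF09827]
      cas9: [PF16595]
  TA:
    components:
      toxin: [PF05016, PF01850]
      antitoxin: [PF04221, PF02604]
  BREX:
    components:
      brxA: [PF20731]
      pglZ: [PF08665]
  DISARM:
    components:
      drmA: [PF00271]
      drmB: [PF13091]
      aaa_atpase: [PF13304]
  ABI:
    components:
      abiEii: [PF08843]
  Zorya:
    components:
      zorA: [PF01618]
      zorB: [PF00771]
  Hachiman:
    components:
      hamA: [PF18742]
      hamB: [PF00580]
  Gabija:
    components:
      gajA: [PF13175]
      gajB: [PF13245]
  Septu:
    components:
      ptuA: [PF13476]
      ptuB: [PF01844]
  Thoeris:
    components:
      thsA: [PF13289]
      thsB: [PF08937]
  Lamassu:
    components:
      lmuA: [PF14130]
      lmuB: [PF02463]
  Druantia:
    components:
      druE: [PF14236]
  Wadjet:
    components:
      jetA: [PF20716]
      jetB: [PF20717]
      jetC: [PF05621]
  Kiwa:
    components:
      kwaA: [PF16162]
  Shedu:
    components:
      sduA: [PF14082]
rm_types:
  PF02384: type_I
  PF01420: type_I
  PF13659: type_II
  PF09517: type_II
  PF01555: type_III
  PF04313: type_I
  PF18766: type_III
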