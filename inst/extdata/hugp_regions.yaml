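# Functional regions of human UDP-glucose pyrophosphorylase, isoform 1
# (hUGP1) author numbering. An isoform 2 structure (11 residues shorter at
# the N-terminus) uses offset -11 against these definitions.
SB_loop:
  ranges: [[286, 293]]        # sugar-binding loop, T286-G293
  numbering_scheme: hUGP1
SB_region:
  ranges: [[282, 327]]        # sugar-binding region, V282-F327
  numbering_scheme: hUGP1
interlock_arg:
  ranges: [[287, 287]]        # R287, interlock donor
  numbering_scheme: hUGP1
interlock_asp:
  ranges: [[456, 456]]        # D456, interlock acceptor on the neighbour
  numbering_scheme: hUGP1
beta23:
  ranges: [[501, 508]]        # C-terminal beta23 strand (end-to-end contact)
  numbering_scheme: hUGP1
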