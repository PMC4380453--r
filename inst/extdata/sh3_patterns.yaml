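# Default SH3 target-motif grammar.
# Symbols: literal residue letter; "+" = K or R; "h" = hydrophobic residue
# (configurable set, default A,V,L,I,M,F,W,Y,P); "x" = any residue.
classI:
  spec: "+hPxxP"
  class: classI
classII:
  spec: "PxhPx+"
  class: classII
PxxDY:
  spec: "PxxDY"
  class: atypical
RxAPxxP:
  spec: "RxAPxxP"
  class: custom
RxLPxxP:
  spec: "RxLPxxP"
  class: custom
RxIPxxP:
  spec: "RxIPxxP"
  class: custom
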