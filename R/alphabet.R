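## Symbol alphabet. Gaps are first-class: they are counted in distributions
## and may be the modal state of a position (rendered as the ABSENT feature).
## This file sorts first so the constants exist when later files' top-level
## code builds the feature-code tables.
SYMBOLS <- c("A", "C", "G", "U", "-")
GAP <- "-"
BASES <- c("A", "C", "G", "U")
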