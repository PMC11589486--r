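# Example registry override for ci_registry(override = ...).
# Entries are expressions in R, G, B; same-named defaults are replaced,
# new names are appended (the registry then exceeds 35 entries).
mio_stRGB: "(R + G + B)/255"
mio_ndRGB: "(R - B)/(R + B + 1)"
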