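# Canonical EV markers: tetraspanins plus cytosolic/ESCRT markers
# commonly assayed under MISEV guidance.
CD9
CD63
CD81
FLOT1
SDCBP   # Syntenin; alias SDCBP is the official gene symbol
TSG101
ALIX    # alias of PDCD6IP
ANXA11
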