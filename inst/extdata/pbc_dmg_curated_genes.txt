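# Manually curated differentially methylated genes in primary biliary
# cholangitis (literature-derived), one symbol per line.
PIN4
NHS
IL1RAPL2
SHROOM2
ATP6AP2
PQBP1
MAGEB2
NSDHL
PIM2
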