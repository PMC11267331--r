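protein_id	term
CON__P001	extracellular space
P003	extracellular exosome
P004	extracellular exosome
P005	extracellular space
P006	nucleus
P007	cytoplasm
P008	extracellular exosome
P009	extracellular space
P010	secretory granule
P011	extracellular vesicle
P012	secretory granule lumen
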