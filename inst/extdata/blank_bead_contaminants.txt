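# Synthetic blank-bead negative-control IP peptide list (example data,
# constructed for demonstrations and tests; not a measured list).
YLLEMLWRL
KLVANNTRL
SIINFEKLA
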