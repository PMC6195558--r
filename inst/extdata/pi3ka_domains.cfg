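# Domain map for the PI3Kalpha p110alpha/p85alpha (niSH2) heterodimer,
# crystal numbering (PDB 4OVU): chain A = p110alpha, chain B = p85alpha.
# Ranges for ABD/RBD/C2/helical/kinase/nSH2/iSH2 follow the community
# assignment of the wild-type dynamical-network partitioning rather than
# strict UniProt domain boundaries; they are recorded as stated.
ABD            = A:1-108
RBD            = A:190-300
C2             = A:335-478
helical        = A:526-643
kinase         = A:699-1067
kinase_nlobe   = A:699-808
kinase_clobe   = A:809-1067
activation_loop = A:933-958
nSH2           = B:322-428
iSH2           = B:429-598
helix_339_347  = B:339-347
helix_400_410  = B:400-410
ialpha3        = B:587-598
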