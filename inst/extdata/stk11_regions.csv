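name,start,end,positions,note
kinase_domain,49,309,,STK11 kinase domain
gxgxxg,56,61,,glycine-rich ATP-orienting loop (GxGxxG)
gxgxxg_glycines,56,61,56;58;61,conserved G positions of GxGxxG
vaik,75,78,,VAIK motif (RAVK in STK11)
vaik_k,75,78,78,catalytic lysine of VAIK
salt_bridge_e98,98,98,,salt-bridging glutamic acid
hrd,174,176,,HRD motif (HKD in STK11)
n181,181,181,,catalytic-loop asparagine
dfg,194,196,,DFG motif (DLG in STK11)
ape,221,223,,APE motif (PPE in STK11)
n_terminus,1,39,,tolerated N-terminal region
c_terminus,341,433,,tolerated C-terminal region
nonsense_core,22,311,,region where truncations are damaging
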