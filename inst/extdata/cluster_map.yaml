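# Functional cluster map: groups GO / Pfam identifiers into named functional
# clusters. This is editable data, not an algorithm — regroup freely.
# Layout: cluster label -> list of IDs (a flat "id: cluster" layout is also
# accepted by load_cluster_map()).
nucleotide binding:
  - GTP_EFTU
  - GTP_EFTU_D2
  - IF-2
  - IF2_N
  - GO:0000166
  - GO:0003676
protein-protein interaction:
  - SH3_3
  - LysM
  - TPR_1
cell wall dynamics:
  - Transgly
  - Transpeptidase
  - NlpC_P60
  - Glucan_synthase
  - GO:0009252
  - GO:0005618
invasion and virulence:
  - Secretin
  - Secretin_N
  - YadA_anchor
  - GO:0009405
iron transport:
  - TonB_dep_Rec
  - Plug
heat-shock:
  - HSP70
  - GrpE
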