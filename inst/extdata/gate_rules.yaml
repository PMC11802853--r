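# Editable B-cell gating rulebook. Feature names refer to columns of the
# feature table handed to gate_cells(); cluster aggregations need a
# `cluster` column. Fractions are expressed on [0, 1].
rules:
  - label: "plasma cell"
    priority: 1
    predicates:
      - {feature: percBCR_high, comparator: ">", threshold: 0.40, aggregation: cell}
      - {feature: PC_score, comparator: ">", threshold: 0.04, aggregation: cell}
  - label: "plasmablast"
    priority: 2
    predicates:
      - {feature: percBCR_high, comparator: ">", threshold: 0.15, aggregation: cell}
  - label: "B cell naive"
    priority: 3
    predicates:
      - {feature: frac_unmutated, comparator: ">", threshold: 0.80, aggregation: cell}
      - {feature: frac_IGHDM, comparator: ">", threshold: 0.98, aggregation: cell}
  - label: "B cell memory"
    priority: 4
    predicates:
      - {feature: CD27, comparator: ">", threshold: 0.1, aggregation: cluster-mean}
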