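# Metacluster annotation rules for the 11 bone/marrow mesenchymal
# populations, expressed as required-high / required-low defining markers.
# Positivity references default to a per-marker two-means split of the
# pooled event intensities (method: split); the CD24 high/low band boundary
# is the two-means split within the CD24-positive subset. Rules are tried in
# priority order (1 = most specific first).
reference: split
rules:
  - population: "Late Osteoblasts/Osteocytes"
    priority: 1
    high: [Sclerostin, Osterix, Runx2]
    low: []
  - population: "CD24high Osteolineage"
    priority: 2
    high: [Osterix, Runx2]
    low: [Sclerostin]
    cd24: high
  - population: "CD24low Osteolineage"
    priority: 3
    high: [Osterix, Runx2]
    low: [Sclerostin]
    cd24: low
  - population: "CD24+/Osterix+"
    priority: 4
    high: [Osterix]
    low: [Runx2]
    cd24: positive
  - population: "ALPL+ Osteolineage"
    priority: 5
    high: [ALPL, Runx2]
    low: [Osterix, Sclerostin]
  - population: "Early Osteoblasts"
    priority: 6
    high: [Runx2, Osterix]
    low: [CD24, Sclerostin, ALPL]
  - population: "Nestin+ Pericytes"
    priority: 7
    high: [Nestin, CD146]
    low: []
  - population: "Perivascular BMSCs"
    priority: 8
    high: [CD146, CD200, Sca-1]
    low: [Nestin]
  - population: "Sca-1/PDGFRa+ BMSCs"
    priority: 9
    high: [Sca-1, PDGFRa]
    low: [CD146]
  - population: "LeptinR+ BMSCs"
    priority: 10
    high: [LeptinR, OsteolectinR]
    low: []
  - population: "Pre-adipocytes"
    priority: 11
    high: [Pparg, Adiponectin]
    low: [LeptinR]
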