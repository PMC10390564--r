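# Default synthetic cohort calibration.
#
# Group-level prevalences, conditional rates and between-animal dispersions
# encode the published cohort summaries for the aged bone/marrow mesenchymal
# compartment:
#   %p16+ of cleaned cells:  young 2.81 +/- 1.32,  old 7.60 +/- 5.60
#   %p21+ of cleaned cells:  young 5.21 +/- 3.27,  old 3.71 +/- 2.96
#   p16KB (p16+/Ki67-/BCL-2+) share of p16+ cells in old mice: 17.44%
#   Ki67- fraction of p16+BCL-2+ cells: ~98%
#   young %p16KB < 0.2% of all cells, old/young fold-change 6.8
#   mean BCL-2 in p16+ cells, old vs young: 1.8-fold
# All intensity levels are means on the arcsinh (cofactor 5) scale; event
# intensities are drawn normal on that scale and inverse-transformed to the
# raw ion-count scale (truncated at zero).
version: default-cohort-1
seed: 1
events_per_sample: 20000
cofactor: 5

# contamination fractions of acquired events
contamination:
  beads: 0.02
  doublets: 0.03
  dead: 0.04
  debris: 0.02
  cd45pos: 0.03

# fractional linear signal drift across the acquisition (peak-to-peak)
drift_slope: 0.10

signals:
  background_mean: 0.2        # arcsinh level of unexpressed markers
  background_sd: 0.3
  positive_sd: 0.35           # arcsinh sd of expressed markers
  bead_raw_signal: 1200       # raw bead-channel ion counts on beads
  bead_raw_cv: 0.05
  dna_mean: 5.5               # arcsinh DNA intercalator, intact singlets
  dna_sd: 0.15
  event_length_raw_mean: 25
  event_length_raw_sd: 2
  bead_event_length_raw_mean: 12
  debris_event_length_raw_mean: 18
  viability_live_mean: 0.3    # arcsinh cisplatin, live cells
  viability_live_sd: 0.25
  viability_dead_mean: 4.5    # dead cells take up cisplatin
  viability_dead_sd: 0.3
  debris_dna_mean: 3.0
  debris_dna_sd: 0.3
  cd45_pos_mean: 4.0          # hematopoietic carryover
  lineage_pos_mean: 3.5
  doublet_multiplier: [1.8, 2.0]   # DNA / event-length multiplier range

# arcsinh levels taken by flag-positive cells on the flagged marker.
# BCL-2 level is set so the mean BCL-2 within p16+ cells rises 1.8-fold from
# young to old given the group BCL-2+ fractions below.
marker_levels:
  p16: 3.0
  p21: 3.0
  Ki67: 4.0
  Ki67_low: 2.6   # residual low-grade Ki67 in otherwise non-proliferative p16+ cells
  BCL-2: 4.11
  FLAG: 2.5

prevalence:
  p16: {young: 0.0281, old: 0.0760, old_senolytic: 0.031}
  p21: {young: 0.0521, old: 0.0371, old_senolytic: 0.035}

# between-animal dispersion: sd of the mean-one lognormal multiplier applied
# to each sample's prevalences, chosen so simulated per-sample sds
# approximate the printed cohort sds
dispersion: {young: 0.4525, old: 0.659, old_senolytic: 0.659}

# marker positivity among cells carrying neither p16 nor p21
base_rates: {bcl2: 0.05, ki67: 0.08}

conditional:
  ki67_pos_given_bcl2_archetype: 0.02   # => ~98% of p16+BCL2+ are Ki67-
  ki67_pos_given_nonki67_archetype: 0.02 # p16-high cells are Ki67-low
  bcl2_given_p21: 0.15
  ki67_pos_given_p21_bcl2: 0.02

# gating defaults: the p16 cutoff comes from a knock-out control at the
# ko_quantile; markers without a knock-out control are cut at a pooled
# young-cohort quantile placed at the expected negative-fraction boundary
# (1 - overall positive fraction implied by the rates above)
thresholds:
  ko_quantile: 0.999
  pooled_quantiles: {p21: 0.9479, BCL-2: 0.9442, Ki67: 0.9111}

# senescence archetypes: families of p16+ cells. weight = fraction of p16+
# cells per group; bcl2_family archetypes are BCL-2+ (young family weight
# 0.0707 and old 0.178 give p16KB shares 6.93% and 17.44% after the 2%
# Ki67+ leak); ki67_family archetypes are Ki67+. shifts are additive arcsinh
# offsets on senescence-panel markers.
archetypes:
  - name: bcl2
    bcl2_family: true
    weight: {young: 0.05, old: 0.12, old_senolytic: 0.05}
    shifts: {p21: 0.8, IL-1a: 1.2, IL-1b: 1.2, pNFkB: 1.0, CXCL1: 1.0, pATM: 1.2, p53: 0.8}
  - name: bcl2_gh2ax
    bcl2_family: true
    weight: {young: 0.0207, old: 0.058, old_senolytic: 0.0207}
    shifts: {p21: 0.8, IL-1a: 1.2, IL-1b: 1.2, pNFkB: 1.0, CXCL1: 1.0, pATM: 2.5, p53: 0.8, yH2A-X: 4.0}
  - name: ki67
    ki67_family: true
    weight: {young: 0.25, old: 0.12, old_senolytic: 0.25}
    shifts: {}
  - name: ki67_inflammatory
    ki67_family: true
    weight: {young: 0.15, old: 0.08, old_senolytic: 0.15}
    shifts: {IL-6: 2.5, MCP-1: 2.5, pNFkB: 2.0}
  - name: inflammatory
    weight: {young: 0.15, old: 0.20, old_senolytic: 0.15}
    shifts: {IL-6: 2.5, IL-1a: 2.5, CXCL1: 2.5, TNFa: 2.0}
  - name: unlabeled
    weight: {young: 0.3793, old: 0.422, old_senolytic: 0.3793}
    shifts: {}

# mesenchymal populations: mixture weights per group, senescence enrichment
# (relative propensity to carry p16; concentrated in late osteoblasts /
# osteocytes and CD24high osteolineage), and identity-marker means (arcsinh;
# unlisted markers sit at background). The senolytic arm depletes the
# CD24high / CD24+Osterix+ / late osteoblast-osteocyte clusters and gains
# early osteoblasts.
populations:
  - name: "LeptinR+ BMSCs"
    weight: {young: 0.22, old: 0.22, old_senolytic: 0.24}
    enrichment: 0.6
    markers: {LeptinR: 3.5, OsteolectinR: 3.5, CXCL12: 3.5, Adiponectin: 2.0}
  - name: "Sca-1/PDGFRa+ BMSCs"
    weight: {young: 0.13, old: 0.13, old_senolytic: 0.14}
    enrichment: 0.6
    markers: {Sca-1: 3.5, PDGFRa: 3.5, Podoplanin: 3.0, CD29: 2.0, CXCL12: 1.5}
  - name: "Perivascular BMSCs"
    weight: {young: 0.10, old: 0.10, old_senolytic: 0.11}
    enrichment: 0.6
    markers: {CD146: 3.5, Sca-1: 3.5, CD200: 3.5, CD29: 3.0, Adiponectin: 2.0}
  - name: "Nestin+ Pericytes"
    weight: {young: 0.06, old: 0.06, old_senolytic: 0.06}
    enrichment: 0.6
    markers: {Nestin: 3.5, CD146: 3.5, CD29: 2.0}
  - name: "ALPL+ Osteolineage"
    weight: {young: 0.09, old: 0.09, old_senolytic: 0.09}
    enrichment: 1.0
    markers: {ALPL: 3.5, Runx2: 3.5, Dmp1: 2.0, CXCL12: 2.0}
  - name: "Early Osteoblasts"
    weight: {young: 0.10, old: 0.10, old_senolytic: 0.16}
    enrichment: 0.8
    markers: {Runx2: 3.5, Osterix: 3.5}
  - name: "Late Osteoblasts/Osteocytes"
    weight: {young: 0.08, old: 0.08, old_senolytic: 0.04}
    enrichment: 4.0
    markers: {Sclerostin: 3.5, Osterix: 3.5, Runx2: 3.5, Dmp1: 3.5, OCN: 2.0}
  - name: "CD24low Osteolineage"
    weight: {young: 0.07, old: 0.07, old_senolytic: 0.07}
    enrichment: 1.5
    markers: {CD24: 2.6, Osterix: 3.5, Runx2: 3.5}
  - name: "CD24high Osteolineage"
    weight: {young: 0.06, old: 0.06, old_senolytic: 0.02}
    enrichment: 4.0
    markers: {CD24: 4.5, Osterix: 3.5, Runx2: 3.5}
  - name: "CD24+/Osterix+"
    weight: {young: 0.05, old: 0.05, old_senolytic: 0.03}
    enrichment: 2.5
    markers: {CD24: 3.5, Osterix: 3.5, Runx2: 0.8}
  - name: "Pre-adipocytes"
    weight: {young: 0.04, old: 0.04, old_senolytic: 0.04}
    enrichment: 1.0
    markers: {Pparg: 3.5, Adiponectin: 3.5}
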