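# End-to-end synthetic analysis: a three-helix bundle analysed in the
# all-atom regime, the same kind of complex in C-alpha-only form analysed
# with calibrated cutoffs, a conservation comparison for chain A, and a
# mirror-tree table over three families on a shared species tree (rate
# scales emulating the outer-coat / adaptor / cargo-proximal layers) plus
# one unrelated baseline family.
seed: 42
output_dir: coatmap_run
n_points: 240
reference: synthetic
neighbor_cutoff: 8.0

structures:
  - scenario: {n_chains: 3, length: 40, geometry: paired-helix, seed: 11}
  - scenario: {n_chains: 3, length: 40, geometry: paired-helix, seed: 12}
    calpha: true

calibration:
  n_complexes: 6
  length: 40
  seed: 101
  min_per_type: 50

n_boot: 2000
conservation:
  families:
    - name: chainA
      scenario:
        n_taxa: 16
        n_sites: 40
        seed: 21
        site_rates: {interface: 0.2, surface: 1.0}
        site_fractions: {interface: 0.3, surface: 0.7}
      structure: 1
      chain: A
      link_to_interface: true

mirror:
  model: poisson
  n_taxa: 16
  n_sites: 300
  tree_seed: 7
  n_perm: 499
  families:
    - {name: clathrin_hc, scale: 0.5, shared: true, seed: 31}
    - {name: beta_adaptin, scale: 1.0, shared: true, seed: 32}
    - {name: mu_adaptin, scale: 2.0, shared: true, seed: 33}
    - {name: unrelated_ap, scale: 1.0, shared: false, seed: 34}
  pairs:
    - {a: clathrin_hc, b: beta_adaptin, role: interacting}
    - {a: clathrin_hc, b: mu_adaptin, role: interacting}
    - {a: beta_adaptin, b: mu_adaptin, role: interacting}
    - {a: clathrin_hc, b: unrelated_ap, role: baseline}
    - {a: beta_adaptin, b: unrelated_ap, role: baseline}
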