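# Bundled data provenance

- `machines_mu1.1.tsv` — actively translating ribosome and EFTu copy numbers in a
  0.064 µm³ reaction volume at growth rate 1.1 h⁻¹, after Rudorf & Lipowsky.
- `trna_mu1.1.tsv` — per-species tRNA copy numbers in the same volume, derived
  from the Dong et al. isoacceptor measurements at growth rate 1.1 h⁻¹.
  Some entries are combined isoacceptor pools (`Tyr1/2`, `Ile`, `Met` is the
  elongator species). Counts are fractional as published; they are rounded to
  integers at simulation start. `Thr1` duplicates `Thr3`'s codon reading and is
  not targeted by the bundled codon map.
- `kinetics.tsv` — ternary-complex diffusion coefficient, first-order
  dissociation rate, maximum ribosome elongation rate (t_cat = 1/24 s), and the
  default burn-in / stop-step counts.
- `codon_trna_map.tsv` — one-to-one assignment of each of the 61 sense codons to
  the single tRNA species that serves it in this model (wobble collapsed onto the
  major isoacceptor; Dong et al. naming).
- `aa_costs_approx.tsv` — APPROXIMATE precursor-excluded amino-acid synthesis
  costs in ATP equivalents (one-letter codes). Used only for generic protein-cost
  book-keeping; the headline per-molecule costs (ribosome 108,461; tRNA 700;
  EFTu 3,565 ATP equivalents) are bundled constants, see `unit_costs()`.
- `tufa_like_synthetic.fasta`, `gfp_like_synthetic.fasta` — SYNTHETIC coding
  sequences produced by `synth_codon_sequence()` (adaptation 1 and 0, lengths
  394 and 238 codons, fixed seeds 101 and 202). They are stand-ins emulating a
  codon-adapted native gene (tufA-like) and a non-adapted heterologous gene
  (GFP-like); they are NOT the real tufA or GFP CDS.
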