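# moblkit

Desk-scale toolkit for delineating a conjugative **relaxase family** (MOB
typing) from a single seed protein, and for annotating the **oriT** region
its members act on. Relaxases nick the origin-of-transfer site- and
strand-specifically and lead plasmid conjugation; families of them are
defined computationally, by iterative profile homology search, conserved
motif ("signature") discovery, and phylogenetic clade analysis. moblkit
re-implements that entire in-silico workflow as tested, reusable R code,
together with ground-truth synthetic-data generators so every stage can be
validated without touching external databases.

The pipeline, mirroring the field's standard practice:

1. **Iterative PSSM search** (`psi_search`): a psi-blast-style profile
   search with empirically calibrated Gumbel E-values,
   `E = K·m·n·exp(−λS)`, inclusion at E ≤ 1e-15, up to 10 rounds,
   monotone membership.
2. **Redundancy reduction** (`greedy_cluster`): greedy centroid clustering
   at identity 1.0 (dedup) and 0.50 (centroids for motif discovery); the
   identity is end-gap-free global alignment identity.
3. **Signature discovery** (`discover_signatures`): ZOOPS
   expectation-maximization motif discovery (up to 10 signatures,
   E ≤ 1e-15, EM-refit null), cross-family scanning (`scan_signature`,
   E ≤ 1e-6) and occurrence tables.
4. **Clade analysis** (`neighbor_joining`, `bootstrap_supports`,
   `split_two_clades`): center-star MSA, Poisson distances, Saitou–Nei
   neighbor joining, 1000 column-bootstrap replicates, condensed trees,
   and the two-clade cut at the best supported×length internal branch.
5. **Plasmid localization** (`translated_match`,
   `clade_plasmid_crosstab`): tblastn-style six-frame matching against
   circular plasmids (identity > 0.95 over > 0.80 of the protein), with a
   clade-by-location crosstab.
6. **oriT annotation** (`curvature_profile`, `find_repeats`,
   `gc_windows`, `locate_nick`): dinucleotide wedge-model intrinsic
   curvature (600-bp smoothed z-profile, mean 0 / sd 1), direct/inverted
   repeats and palindromes, GC windows, and localization of the nic-site
   recognition 14-mer 5'-GAATCGGGGGCCGG-3'.
7. **Hydrodynamics** (`svedberg_mass`, `frictional_ratio`): the Svedberg
   relation M = RTs/((1−v̄ρ)D) and the frictional ratio f/f₀ against the
   equivalent anhydrous sphere.

## Worked example

Generate a synthetic two-clade family (60 members, one universal signature
and two clade-biased ones) plus 500 unrelated decoys, then run the whole
pipeline:

```r
library(moblkit)

fam <- gen_family(family_spec(), seed = 42)         # 30 + 30 members
dec <- gen_decoys(500, seed = 43)
db  <- seq_set(c(fam$seqs$seqs, dec$seqs),
               c(fam$seqs$ids, dec$ids), "protein")

res <- psi_search(fam$seqs$seqs[1], db, evalue_threshold = 1e-15, seed = 1)
length(res$members)                                  # how many accepted?
mean(res$members %in% fam$seqs$ids)                  # precision

sigs <- discover_signatures(fam$seqs, width_range = c(6, 12), seed = 1,
                            max_motifs = 3)
sigs[[1]]
```

Output from this exact session:

```
> length(res$members)
[1] 60
> mean(res$members %in% fam$seqs$ids)
[1] 1
> sigs[[1]]
signature sig1 : width 8 , E = 3.5e-52 , 60 sites
consensus: HIHEKHTH
```

All 60 planted family members are recovered with no decoy (recall 1.0,
precision 1.0 at E ≤ 1e-15), and the first signature is exactly the
histidine-rich motif planted in every member — the analog of the universal
metal-binding signature that anchors the real family. The Svedberg worked
example, with the buffer-derived density (1.022 g/mL) and v̄ = 0.730 mL/g:

```
> svedberg_report(s = 2.8, D = 56.7)$mass_da
[1] 47462.31
> frictional_ratio(50329, 3.3, 0.73)
[1] 1.489548
```

i.e. a ~47.5 kDa apparent monomer mass (within 1% of the published 47,760
Da for the same measurements) and a moderately elongated monomer
(f/f₀ ≈ 1.5).

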