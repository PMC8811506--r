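# homeologdiv

Quantifying the fate of duplicated genes after allopolyploid whole-genome
duplication.

## The problem

An allotetraploid genome, such as that of the African clawed frog *Xenopus
laevis*, carries two diverged parental subgenomes (L and S). Each gene of the
diploid relative (*X. tropicalis*) may survive as a **homeolog pair** (one
copy per subgenome, suffixes `.L`/`.S`), as a **singleton** (one copy lost),
or disappear entirely. For gene families under fast evolution — the chemokine
ligands and their receptors are the motivating case — three questions follow:

1. **Retention** — what fraction of the diploid gene set survives on each
   subgenome, and how many homeolog pairs remain?
2. **Expression divergence** — do the two copies of a pair still behave the
   same? Expression profiles over developmental stages or adult tissues are
   compared per pair with Pearson's correlation (profile shape) and a paired
   Student *t* test (expression level) on floored, `log2(TPM + 1)`-transformed
   data, giving a four-way category:
   - **HCSE** — high correlation (*p* ≤ 0.05), same level (*p* > 0.05)
   - **HCDE** — high correlation, different level (*p* ≤ 0.05)
   - **NCSE** / **NCDE** — no correlation (*p* > 0.05) × same/different level
   A pair whose profiles never exceed 0.5 TPM is `n/a`. Two biological
   replicate clutches are classified independently; disagreements are
   labelled inconsistent (`inc`), annotated with the axis the clutches agree
   on (e.g. `inc:HC`).
3. **Sequence divergence** — is either copy evolving under relaxed or
   positive selection? The package estimates pairwise dN/dS (ω) by
   synonymous/nonsynonymous counting: per-codon site fractions, equal-weight
   enumeration of the mutational pathways between differing codons (stop-free
   pathways only), and Jukes–Cantor correction
   `d = -3/4 · ln(1 − 4p/3)` of both proportions, with `ω = dN/dS`. Copies
   with ω strictly above 1 are flagged as candidates for positive selection
   or relaxation.

Seeded simulators generate two-clutch expression matrices with controlled
correlation/offset structure and codon alignments evolved at a target ω, so
every stage of the pipeline is testable with known truth.

The packaged catalog (`inst/extdata/chemokine_catalog.tsv`) covers the
*X. laevis* chemokine ligand/receptor repertoire: per-gene subgenome
presence, homeolog peptide identity, per-copy dN/dS, and the per-analysis
expression categories.

## Worked example

```r
library(homeologdiv)

## 1. catalog accounting
catalog <- read_catalog()          # packaged chemokine catalog
summary(catalog)
```

```
ligand: 52 genes (22 pairs + 8 singletons)
  retention: L 28/30 (93%), S 23/30 (77%)
  mean homeolog identity: 76.86% (rounded 77%) over 21 pairs
  dN/dS > 1: 4/22 pairs [ccl21.S, cxcl18.S, cxcl8b.1.S, xcl1.L]
receptor: 26 genes (9 pairs + 8 singletons)
  retention: L 17/17 (100%), S 9/17 (53%)
  mean homeolog identity: 87.67% (rounded 88%) over 9 pairs
  dN/dS > 1: 0/9 pairs
tissue categories:    HCSE=6 HCDE=10 NCSE=0 NCDE=3 n/a=0 inc=10 unlabeled=19
embryonic categories: HCSE=1 HCDE=1 NCSE=1 NCDE=0 n/a=24 inc=4 unlabeled=17
```

The ligand repertoire keeps 52 genes (22 pairs, 8 singletons); 28 of the 30
diploid-reference ligands survive on L (93%) and 23 on S (77%); four ligand
copies — and no receptor copy — carry dN/dS above 1.

```r
## 2. expression divergence on simulated data with known truth:
##    strongly correlated profiles with an 8-fold (3 log2-unit) offset
sim <- simulate_expression(6, rho = 0.95, offset_log2 = 3,
                           noise_sd_log2 = 0.1, seed = 7)
classify_homeologs(sim$clutch_t, sim$clutch_u)
```

```
Homeolog expression classification: 6 pairs (alpha = 0.05, TPM floor = 0.5)
final categories: HCSE=0 HCDE=6 NCSE=0 NCDE=0 n/a=0 inc=0
```

All six pairs are recovered as HCDE — correlated in shape, different in
level — exactly the structure that was simulated.

```r
## 3. dN/dS on a codon alignment evolved at target omega = 2
aln <- simulate_codon_pair(300, omega_target = 2,
                           branch_subs_expected = 60, seed = 11)
estimate_dnds(aln$seq_a, aln$seq_b, ids = c("sim.L", "sim.S"))
```

```
dN/dS estimate (sim.L vs sim.S), 300 codons (0 excluded)
  sites  S = 239.25  N = 660.75
  diffs  Sd = 11.00  Nd = 62.00  (pS = 0.0460, pN = 0.0938)
  dS = 0.04745  dN = 0.1002  omega = 2.113
```

The counting estimator recovers ω ≈ 2.1 for a pair evolved at target 2, and
`dnds_screen()` flags it at the ω > 1 threshold.

A command-line interface wraps the same functions
(`exec/homeologdiv`): `catalog summarize`, `expression classify`,
`dnds estimate`, `dnds screen`, `simulate expression`, `simulate codons`.

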