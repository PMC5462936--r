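# sigdnds

Signature-aware dN/dS estimation for cancer somatic mutation data.

## The problem

The dN/dS ratio — non-synonymous substitutions per non-synonymous site over
synonymous substitutions per synonymous site — is the standard way to read
selection off coding mutations: values below 1 suggest purifying selection,
above 1 positive selection. Its basic form assumes every possible base
substitution is equally likely. Tumors violate this badly: mutational
processes such as UV exposure concentrate mutations in particular
substitution classes (in melanoma, ~88% of somatic mutations are C>T,
mostly at dipyrimidine TpC contexts). Because the redundancy of the genetic
code concentrates *synonymous opportunity* in exactly those classes, a
skewed signature pushes the basic dN/dS below 1 in the complete absence of
selection — most strongly in genes rich in NTN codons (thymine at the
second codon position, all 16 of which encode hydrophobic amino acids),
i.e. membrane-protein genes. The result is a false signal of purifying
selection.

`sigdnds` is for analysts of somatic mutation catalogs who want
selection estimates that are not confounded by the mutational signature.

## The model

Mutations are classified into the 6 pyrimidine-referenced substitution
classes (C>A, C>G, C>T, T>A, T>C, T>G) or their 96 trinucleotide
refinements `X[R>A]Y`. For a gene with `n` observed non-synonymous and `s`
synonymous mutations, `N` non-synonymous and `S` synonymous sites
(enumerated by simulating all three possible point mutations at every CDS
position), the estimators are

    basic     dN/dS = (n/N) / (s/S) = (n/s) · (S/N)
    corrected dN/dS = (n/s) / (N_MS / S_MS),   N_MS = Σ_i N_i·P_i,  S_MS = Σ_i S_i·P_i
    simulated dN/dS = (N_MS / S_MS) / (N / S)

where `N_i`, `S_i` are the per-class site counts and `P_i` the signature
probability of class `i`. The simulated dN/dS is the value a gene is
expected to show from the signature alone, with no selection; the three
quantities satisfy `corrected = basic / simulated`. Per-gene purifying
selection is tested with a one-tailed binomial test on the non-synonymous
fraction, with Benjamini–Hochberg FDR control across genes, and gene-set
enrichment uses Fisher's exact test.

A synthetic-cohort generator (`simulate_cohort()`) produces in-frame genes
with controllable NTN-codon content and signature-driven mutation catalogs
with a known purifying-selection strength `f`, so that the whole chain can
be validated end to end: the corrected dN/dS of such a cohort recovers
`1 − f`.

## Worked example

A melanoma-like cohort (100 genes, ~250 mutations/gene, 87.6% C>T mass,
30% of non-synonymous events removed by purifying selection):

```r
library(sigdnds)

cohort <- simulate_cohort(
  n_genes = 100, n_codons = c(100, 300),
  signature = melanoma_like_signature("96"),
  mutations_per_gene = 250, selection_strength = 0.3, seed = 42
)
fit <- dnds_select(cohort$mutations, cohort$genes,
  signature = cohort$signature, quiet = TRUE
)
fit
#> Signature-aware dN/dS selection analysis
#>   19910 mutations; 100 genes with >= 10 mutations
#>   median dN/dS: basic 0.475, corrected 0.706, simulated 0.703
#>   74 gene(s) significant at 5% FDR (corrected metric, one-tailed 'less')
```

The basic dN/dS (median 0.475) wildly overstates purifying selection: most
of the deficit of non-synonymous mutations is the C>T signature talking
(simulated dN/dS 0.703). The corrected median 0.706 recovers the true
selection level, 1 − f = 0.7. Per-gene detail comes from `tidy(fit)`:

```r
head(tidy(fit), 4)
#> # A tibble: 4 × 13
#>   gene_id     n     s     N     S  N_ms  S_ms dnds_basic dnds_corrected
#>   <chr>   <int> <int> <int> <int> <dbl> <dbl>      <dbl>          <dbl>
#> 1 g0001     110    92  1837   557 17.2   9.48      0.363          0.657
#> 2 g0002     132    82  1001   322  9.45  4.33      0.518          0.738
#> 3 g0003     126    74  1242   414 12.3   5.51      0.568          0.763
#> 4 g0004     121    88  1697   553 16.4   8.11      0.448          0.682
```

and `signature_sweep()` shows how the bias grows with the C>T probability:

```r
signature_sweep(site_spectra(cohort$genes[1:10, ]), "C>T", c(1/6, 0.5, 0.876))
#> # A tibble: 3 × 4
#>   sweep_class probability dnds_simulated n_genes
#>   <chr>             <dbl>          <dbl>   <int>
#> 1 C>T               0.167          1          10
#> 2 C>T               0.5            0.835      10
#> 3 C>T               0.876          0.696      10
```

`glance(fit)` gives the one-row cohort summary, `autoplot(fit)` the
basic-versus-corrected histogram, and `plot_signature()` /
`plot_sweep()` the usual signature and sweep figures. A thin command-line
wrapper with `signature`, `dnds`, `sweep`, `enrich` and `synth`
subcommands is installed at `inst/cli/sigdnds.R`.

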