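# shmrep

Somatic hypermutation (SHM) analysis for immunoglobulin heavy-chain
repertoires sequenced against a single germline V segment.

## The scientific problem

Antigen-activated B cells diversify their rearranged immunoglobulin variable
genes through SHM, a point-mutation process initiated by activation-induced
cytidine deaminase (AID). AID leaves a characteristic statistical signature:

* an excess of **transitions** (A↔G, C↔T) over transversions;
* mutations concentrated in **hotspot 5-mer motifs** — W̲R̲C/GY̲W̲ and W̲A/TW̲
  (W = A/T, R = A/G, Y = C/T, S = C/G; the mutated base underlined is the
  5-mer centre) — and depleted in S̲Y̲C/GR̲S̲ coldspots;
* when the mutated cells are additionally *antigen-selected*, an enrichment of
  replacement (amino-acid-changing) over silent mutations in the
  complementarity-determining regions, summarised by per-region **R/S
  ratios** (R/S > 3 in CDRs vs < 2 in frameworks is the classic selected
  pattern; replacements spread across the frameworks with low CDR R/S argue
  against selection).

`shmrep` implements the full informatics chain needed to measure these
signatures in a repertoire amplified from one canonical germline V gene, the
design used in hapten-response studies of mouse plasma cells:

1. **Alignment & filtering** — semi-global alignment of each read to the
   germline V, strict >90 % identity filter, productivity filter (full-length,
   in-frame, stop-free, indel-free).
2. **Clonal grouping** — clones are sets of reads sharing an identical CDR3
   junction nucleotide string.
3. **Consensus** — one majority-vote consensus per clone, so a mutation shared
   by clonal siblings is counted once.
4. **Mutation analysis** — per-mutation classification
   (transition/transversion, hotspot context, replacement/silent by region),
   background-adjusted per-5-mer mutabilities ("hedgehog" data:
   `mutations(m) / background(m)`, normalized to background-weighted mean 1),
   hotspot/coldspot fractions, per-region R/S, and per-sequence mutation
   loads.
5. **Lineage trees** — germline-rooted minimum-mutation trees per clone with
   inferred intermediate nodes, exported as Newick.
6. **Assay kinetics** — plasma-cell half-lives by log-linear regression
   (`t½ = ln 2 / |slope|`), slope-equality t-tests, and virus neutralization
   titres from OD450 dilution series using the 50 % specific-signal rule.
7. **Synthetic repertoires** — a generator with full ground truth (clone
   partition, per-read mutation lists, lineage edges, sequencing errors) so
   every stage is testable without external data.

## Worked example

```r
library(shmrep)

ref <- synthetic_reference()          # packaged 294-nt synthetic germline V
cfg <- pipeline_config(
  simulation = list(
    model = targeting_model(hot_mutability = 5, cold_mutability = 0.2,
                            transition_fraction = 0.6),
    config = list(n_clones = 12, mutations_per_lineage_step = 1.5)),
  seed = 42)
report <- run_pipeline(cfg)
report
#> <shm_report>
#>   filter funnel: input=97 -> full_length=97 -> productive=91 -> homology=91
#>   clones: 12; consensus mutations: 26; trees: 10
#>   hotspot/neutral/coldspot: 88.5% / 11.5% / 0.0%
#>   transitions: 53.8%
```

The funnel shows 97 simulated reads, of which 91 were full-length, productive
(six acquired a stop codon through SHM and were excluded) and above the 90 %
germline-identity threshold. The 91 reads fall into the 12 simulated clones;
their consensuses carry 26 distinct mutational events, 88.5 % of which sit in
AID hotspot contexts — the enrichment the targeting model put in
(hot:neutral = 5:1 on a germline whose scored positions are ~38 % hotspot).

```r
report$hotspot_fractions
#> # A tibble: 3 × 3
#>   context_group     n fraction
#> 1 hotspot          23    0.885
#> 2 neutral           3    0.115
#> 3 coldspot          0    0

write_newick(report$trees[[1]])   # germline-rooted Newick, weights = mutations

s <- simulate_decay_series(1000, 86, seq(0, 210, 30), cv_noise = 0.2, seed = 42)
estimate_half_life(s)
#> <half_life_fit> t1/2 = 84.7 days (slope -0.008179/day, R^2 0.947, n=8)
```

A command-line wrapper with `simulate`, `analyze`, `trees`, `report` and
`kinetics` subcommands is installed at
`system.file("scripts", "shmrep-cli.R", package = "shmrep")`.

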