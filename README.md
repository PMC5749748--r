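# dwdmine

Genome-wide discovery, classification and phylogenetics of **DWD
proteins** — WD40-repeat proteins that carry the 16-residue
DDB1-binding (WDxR) motif and act as substrate receptors of CUL4-RING
E3 ubiquitin ligases.  Surveys of plant and algal proteomes repeatedly
need the same analysis: find the WD40 proteins, scan them for the DWD
motif, type their domain architectures, compare them to an annotated
reference repertoire, and place their motifs on a tree.  `dwdmine`
packages that analysis for R users working on proteome-scale FASTA
input, with a seeded simulator so every stage can be validated against
planted ground truth.

## The model at the core

A protein is called WD40 when its sequence contains a chain of at least
`min_repeats` units of 40–60 residues, each ending in the Trp-Asp
(`WD`) dipeptide (or when a precomputed annotation says so).  Within
WD40 proteins, the DWD motif is a hard 16-position consensus:

```
[IFVL]-[IFVL]-[AGST]-[AGST]-[AGST]-x-[DE]-x-x-[IFVL]-x-[IFVL]-[WY]-[DE]-[IFVL]-[RK]
```

Under a uniform residue background the per-window match probability is
(4/20)^8 · (2/20)^4 = 2.56e-10, so random sequence essentially never
matches — the scanner needs no score threshold.  Motif occurrences are
labelled D1/D2/D3 from the N-terminus; records are typed A–K from motif
position, motif count and accessory-domain topology; motif 16-mers are
compared by p-distance and clustered with neighbor joining (Saitou–Nei,
1,000 bootstrap replicates by default); queries are characterized
against a reference DWD database by affine-gap global alignment
(BLOSUM62, gap 11/1) percent similarity.  The methods vignette
(`vignettes/dwd-discovery-methods.Rmd`) documents every model choice,
default and limitation.

## Worked example

Simulate a three-species dataset with planted truth, then run the full
pipeline:

```r
library(dwdmine)

cfg <- sim_config(seed = 42, n_wd40_per_species = 50)
sim <- cmd_simulate(cfg, "demo_data")
#> simulate: wrote 150 proteins for 3 species to demo_data

rc <- run_config(
  input_fastas = file.path("demo_data", c("sp1.fasta", "sp2.fasta", "sp3.fasta")),
  outdir = "demo_out", n_boot = 100, k_groups = 10, seed = 42)
out <- cmd_run_all(rc)
#> inputs: 150 proteins, 3 species
#> detect: 150 WD40 proteins
#> scan: 87 DWD proteins, 102 motif hits
#> classify: 87 records, 5 types
#> phylo: 87 motif leaves, 10 groups
#> stats: 3 species

head(out$hits, 5)
#>    protein_id species ordinal start_1based        motif_seq
#> 1 sp1_fam0001     sp1      D1          104 FVSAADERRIYIYELR
#> 2 sp1_fam0004     sp1      D1          206 IITGTAEMDILLYELK
#> 3 sp1_fam0007     sp1      D1          196 ILGASQDVVIYVYEFR
#> 4 sp1_fam0010     sp1      D1          137 VIGSAEEKKLLVWELR
#> 5 sp1_fam0011     sp1      D1          141 VVAGSSDYVFAFWDLK

out$stats
#>   species n_wd40 n_dwd dwd_ratio_pct    frac_1    frac_2 frac_3plus
#> 1     sp1     50    29            58 0.8275862 0.1724138          0
#> 2     sp2     50    29            58 0.8275862 0.1724138          0
#> 3     sp3     50    29            58 0.8275862 0.1724138          0
#> 4  pooled    150    87            58 0.8275862 0.1724138          0
```

Reading the output: all 150 simulated proteins are detected as WD40;
87 of them carry at least one DWD motif (a 58% DWD/WD40 ratio — the
simulator draws DWD families at 55%), and ~83% of DWDs have a single
motif, matching the configured 1/2/3-motif mix (0.76, 0.21, 0.03) at
this sample size.  `start_1based` prints motif positions in the
biologists' 1-based convention; everything in memory is 0-based
half-open.  `demo_out/` additionally contains the repeat-region,
type-distribution, tree (`motif_tree.nwk`, with bootstrap supports as
internal labels) and group-assignment files, all as TSV/Newick/JSON.

A thin command-line wrapper with the same two subcommands is installed
at `inst/scripts/dwdmine`:

```sh
Rscript inst/scripts/dwdmine simulate --config sim.json --outdir data
Rscript inst/scripts/dwdmine run-all  --config run.json --force
```

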