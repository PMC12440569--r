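# troykascan

Structural characterization of **Troyka LTR retrotransposons** — a deeply
divergent superfamily of LTR retroelements in marine animals that breaks the
rules the canonical superfamilies follow. Where Gypsy/Metaviridae, Copia,
BEL and the retroviruses carry 5′-TG … CA-3′ LTR termini and generate 4–6 bp
target site duplications (TSDs), Troyka LTRs carry 5′-CG … CG-3′ termini
(typically the pentamers 5′-CGCCA … TGGCG-3′) and generate 3 bp TSDs, and
the Gag zinc knuckle is CX₂CX₈₋₁₀HX₄C instead of CX₂CX₄HX₄C. These
structural signatures are the superfamily's diagnostic characters, and
recovering them reliably from raw genomic copies is what this package does.

It is written for repeat curators and comparative genomicists who need the
full characterization procedure as reproducible code rather than manual
steps:

* **Family clustering** — single linkage over genomic repeat copies at 75%
  length coverage (of the shorter sequence) and 75% alignment identity.
* **Majority consensus with flank elongation** — 50% majority-rule consensus
  per cluster, iteratively rebuilt from up to 10 best genomic copies
  extracted with flanking sequence until both LTRs are covered.
* **Joint LTR/TSD boundary calling** — element boundaries placed where the
  terminal repeat pair, an exact 3–6 bp flanking duplication and the
  terminal motifs agree; Repbase-style `-LTR` / `-I` record splitting.
* **Terminal signatures** — per-LTR pentamer classes (canonical, single
  transition, single transversion, multi), per-position substitution
  tallies, and the superfamily call from terminal dinucleotides + TSD
  length.
* **Zinc-finger scan** — both knuckle spacings on Gag translations.
* **Recent-activity screen** — families whose copies average strictly >99.9%
  identity to the consensus.
* **Empty-site analysis** — pre-insertion allele reconstruction (element
  plus exactly one TSD copy removed) and orthologous-locus validation in a
  sibling genome.
* **Simulator** — synthetic genomes with planted elements and exact ground
  truth, so every stage above is tested against known coordinates.

## Worked example

Simulate two families (5–8 copies each, 1% per-copy divergence) with a
sibling genome in which half the loci are empty, then run the pipeline from
LTR-truncated initial hits — the situation a protein-level homology search
leaves you in:

```r
library(troykascan)

cfg <- simulation_config(seed = 42, n_families = 2,
                         copies_per_family = c(5, 8),
                         background_length = 120000)
sim <- simulate_genome(cfg)
set.seed(42)
hits <- initial_hit_table(sim)
res <- run_pipeline(sim$genome, hits, pipeline_params(flank_bp = 500),
                    sibling = sim$sibling)
head(res$loci[, c("family_id", "start", "end", "tsd_len", "tsd_seq",
                  "pentamer5", "pentamer3", "superfamily", "sibling_match")], 7)
```

```
  family_id  start    end tsd_len tsd_seq pentamer5 pentamer3  superfamily   sibling_match
 cluster001  84310  92498       3     GTC     CGCCA     TGGCG       troyka empty_confirmed
 cluster001  21959  30146       3     ACG     CGCCA     TGGCC unclassified        occupied
 cluster001  44200  52389       3     CCG     CGCAA     TGGCG       troyka empty_confirmed
 cluster001 101363 109554       3     CGC     CGCCA     TGGCG       troyka        occupied
 cluster001  72340  80524       3     CAG     CGCCA     TGGCG       troyka empty_confirmed
 cluster001    645   8833       3     AGG     CGCCA     TGGCG       troyka        occupied
 cluster001 172454 180649       3     TAC     CGCCA     TGGCG       troyka empty_confirmed
```

Each row is one genomic copy: its element interval (0-based half-open), the
duplicated target site read off the flanks (`tsd_len`/`tsd_seq` — note each
locus has its own TSD, as insertion sites differ), the terminal pentamers,
the superfamily call, and whether the orthologous locus in the sibling
genome is occupied or confirmed empty. Two loci show post-insertion
mutations in a terminal pentamer (TGGCC, CGCAA); one of them keeps its
CG..CG dinucleotides and stays classifiable, the other drops to
`unclassified` — exactly the evidence trail a curator would want.

Family-level results live in `res$families` (elongated consensus with
per-column depths, recent-activity screen, superfamily call), and
`run_pipeline(..., out_dir = "out/")` writes consensus FASTA, BED6, a locus
TSV and a JSON run manifest. A thin command-line wrapper with `simulate` and
`run` subcommands is installed at `inst/scripts/troykascan.R`.

## Documentation

The methods vignette (`vignettes/troyka-characterization.Rmd`) describes the
model and its assumptions, what the simulator does and does not emulate, the
alignment engine, every numerical choice (scoring weights, tie-breaks,
elongation stop rule, empty-site tolerances) and known limitations.
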