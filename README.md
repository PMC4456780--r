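# primap

Batch PCR primer design with thermodynamic filtering, exact-match
specificity screening, and graphical primer-to-target maps.

`primap` is for anyone who needs primers *en masse* — validating candidate
genes from RNA-seq experiments, genotyping newly sequenced species, primer
walking, assembly PCR, multi-gene-family work. From a multi-FASTA file of any
size it designs forward and reverse primers per target under user-set
constraints, writes a TSV report, and renders a per-primer alignment panel
(PNG/JPEG/GIF) plus a per-target distribution map showing every primer as an
arrowed glyph on a scaled coordinate ruler, each image with a
machine-readable JSON sidecar.

## The model and algorithm

Melting temperatures come from the two-state nearest-neighbor model with the
unified duplex parameters (SantaLucia 1998):

    Tm = 1000 ΔH / (ΔS + R ln(C_T / x)) − 273.15 + 16.6 log10[Na+]

where ΔH = ΔH_init + Σ ΔH(stack) (kcal/mol), ΔS likewise in cal/(mol·K)
with a symmetry correction for self-complementary oligos, R = 1.987
cal/(mol·K), x = 4 (1 if self-complementary), and defaults C_T = 250 nM,
[Na+] = 50 mM.

Per target, every substring with length in `[len_min, len_max]` inside the
5′ search window (forward) or the 3′ window (reverse; sequence taken as the
reverse complement of the covered slice) is enumerated, filtered on length,
GC% range, Tm range and the 3′ GC clamp, then screened for specificity: a
primer is kept iff it has exactly one strand-aware exact binding site
(counting both the oligo and its reverse complement, overlaps included)
across the whole input file — or just its own target, if you prefer.
Accepted primers are named by start position and verified by re-extraction
before any rendering.

## Worked example

```r
library(primap)
fa <- system.file("extdata", "test_seqs.fasta", package = "primap")
recs <- read_fasta(fa)
sets <- design_primers(recs, design_params(five_prime_window = 60,
                                           three_prime_window = 60))
sets[["demo_1"]]
#> <primer_set> demo_1 (548 nt): 29 primer(s)
#>     name direction start end length    tm    gc
#>       25   forward    25  48     24 52.65 50.00
#>       29   forward    29  52     24 52.84 50.00
#>      489   reverse   489 508     20 52.40 60.00
#>      492   reverse   492 515     24 56.74 58.33
#>  493R.22   reverse   493 514     22 54.54 59.09
#>  ...
```

Each row is one accepted primer: `name` is its start position on the target
(suffixed when several primers share a start), `start`/`end` are 1-based
inclusive target coordinates, `seq` (not shown) is the 5′→3′ synthesis-
orientation sequence, `tm` is the nearest-neighbor melting temperature in °C
and `gc` the GC content in percent. Here the 60-nt search windows admit two
forward primers near the 5′ end and a cluster of reverse primers tiling the
3′ window; all satisfy 40–60% GC, 52–65 °C Tm and the GC clamp, and each has
a unique binding site across all five demo records.

A single Tm, for reference:

```r
calc_tm("AGCGTAAGCTTGGCACGTTA")
#> [1] 50.28377
```

### Command line

```sh
primap -a test_seqs.fasta                 # defaults, like the R calls above
primap -a seqs.fa -b 100 -c 100 -e 20 -d 22 -f Y -g 60 -h 40 -i 65 -j 52 -k Y \
       -o out --panel-format gif --audit
primap --synthetic demo.fasta --n-records 10 --seed 7   # make demo input
```

Flags `-a`…`-k` set input, 5′/3′ search windows, length max/min, GC clamp
(Y/N), GC max/min, Tm max/min and the specificity scope (Y = whole file,
N = own sequence); every flag has a long form (`--help` lists them, with
defaults). Outputs land in `-o`: `primers.tsv`, `panels/`, `maps/`,
`alignments/` (CLUSTAL-like text views), plus `rejected_candidates.tsv`
under `--audit`. Exit codes: 0 success (even if some records yield no
primers), 2 usage error, 3 malformed input, 1 otherwise.

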