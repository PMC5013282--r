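---
title: "Detecting and classifying parvovirus-related sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying parvovirus-related sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parvoscreen)
```

## The problem

Parvoviruses (family *Parvoviridae*) are small ssDNA viruses whose traces
turn up in two very different forms in public sequence data: transcripts of
actively replicating (extant) viruses, and endogenous viral elements (EVEs)
— copies integrated into host germline genomes, sometimes recently and
intact, more often anciently and degraded into "fossils" riddled with stop
codons, frameshifts and flanking transposable elements (TEs). parvoscreen
implements a desk-scale pipeline that takes a reference panel of parvoviral
NS (non-structural, SF3-helicase-bearing) and VP (capsid) proteins, screens
transcriptome and genome assemblies for parvovirus-related sequences
(PRSs), gathers integration and degradation evidence, triages likely
cross-sample contaminants, and places the SF3 helicase domains of the
survivors on a bootstrapped phylogeny.

Because the search databases such screens were historically run against are
moving targets, the package validates itself on a synthetic planted-truth
benchmark: a generator plants every event category in simulated hosts and
records the ground truth, and the test suite scores the pipeline against
that truth table end to end.

## Stage 1 — homology search and PRS calling

The search engine is a seeded local aligner in three modes: protein vs
six-frame-translated nucleotide (the workhorse), protein vs protein, and
nucleotide vs nucleotide. Translation uses the standard genetic code with
`*` for stops and `X` for any codon containing `N`. Seeding uses exact
words (3 aa / 11 nt); each seed is extended ungapped under an X-drop rule,
seed diagonals are clustered into candidate loci, and clusters whose best
ungapped segment reaches a gapped-extension gate get a banded affine
Smith-Waterman extension (BLOSUM62, gap open 11 / extend 1 for protein;
+2/−3 with gaps 5/2 for nucleotide). The gate adapts to the minimal score
that could still satisfy the caller's E-value cutoff (45% of it, capped at
raw 40 and floored at the seed trigger), which keeps genome-scale scans
fast without losing the weak chance alignments that E-value calibration
depends on. Overlapping hits on one query-target pair are reduced to the
highest-scoring non-overlapping set; "overlap" tolerates up to one shared
codon, because the two genuine alignments flanking a frameshift abut with
a one-codon overlap and both sides must survive for frameshift evidence
to exist downstream.

Significance uses Karlin-Altschul statistics, `E = K·m·n·exp(−λ·s)`, with
the standard gapped parameters (λ = 0.267, K = 0.041 for BLOSUM62 11/1;
0.625/0.41 for the nucleotide scheme). `evalue()` exposes exactly that
formula. The search stages additionally apply the standard finite-length
("edge effect") adjustment — subtracting from `m` and from each database
sequence a length `l` solving `l = ln(K(m−l)(n−Nl))/H` — because at the
desk scales this package targets, raw `m·n` overstates the search space by
2-3x. With the adjustment, shuffled-database nulls yield hit counts at
`E < t` within a few tens of percent of `t` per search at `t = 0.1`; in
the deeper tail (`t = 0.01`) counts run about 0.5-0.8x nominal, a known
cost of exact-word seeding (no neighbourhood words): some weak chance
alignments simply contain no exact 3-mer. We keep exact seeds for
determinism and simplicity and accept the slightly conservative tail.

PRS calling is two-sided. Forward: every panel protein is searched against
each dataset, keeping hits at `E <= 1e-3`. Reciprocal: forward hits on one
target are merged into loci (same frame sign, gaps < 300 nt), and each
locus is searched back against the panel mixed with a decoy protein set;
the locus is confirmed only if its single best reciprocal hit is a panel
protein at `E <= 1e-3`. The decoy set stands in for the non-viral bulk of
a real protein database; the benchmark's decoys include distant relatives
of the panel ancestor precisely so that "closer to something non-viral"
is a reachable outcome. Confirmed NS and VP loci within 6 kb on one
target (a typical parvovirus genome span) merge into a single `NS_VP`
record. ORFs are called by an exhaustive six-frame scanner; per stop-free
codon stretch one call is made, anchored at the first ATG after a stop or
truncated at the sequence edge, and only ORFs strictly longer than 300 nt
are reported (an ORF of exactly 300 nt is excluded).

## Stage 2 — endogenization evidence

Each PRS is cross-referenced against the genome datasets in nucleotide
mode; a genomic match is stored only when identity over aligned columns is
at least 0.95 **and** `E <= 1e-5`. For matched loci the pipeline collects:

* **internal stops** — the locus is re-aligned with the PRS's reference
  protein and `*` residues strictly inside the aligned region are counted;
  a stop at the final aligned codon is the biological terminator, not
  evidence of degradation. Loci shorter than 60 nt yield "evidence
  unavailable" (NA), never a silent zero.
* **frameshifts** — suspected when a colinear chain of two hits in
  different frames beats the best single-frame alignment by more than 15
  raw score units (about one strong residue run; the margin is ours, as no
  quantitative frameshift rule is standard).
* **TE flanks** — up to 500 nt on each side (clipped at contig ends, which
  sets a scaffold-edge flag) are searched against a TE library; a side is
  flagged when a hit covers at least 80 nt at 80% identity or better.
  These thresholds are our concretisation of "scan the flanks for TEs";
  they are deterministic and testable. An empty library leaves the flags
  NA ("unscanned").
* **intact NS+VP** — true when the locus region carries COMPLETE (hence
  stop-free) ORFs covering at least 80% of both an NS-class and a
  VP-class aligned region.

## Stage 3 — classification and contamination triage

Identity to the best reference protein is binned as `[0, 0.30)`
NOVEL_LINEAGE (below the ICTV genus demarcation of 30% NS1 identity),
`[0.30, 0.85]` INTERMEDIATE, `(0.85, 1]` KNOWN_VIRUS_LIKE; both boundary
values fall in the middle bin. Origin follows priority rules: genomic
match plus any degradation evidence is ENDOGENOUS_DEGRADED; a scaffold-edge
match without degradation evidence is AMBIGUOUS (the flank context needed
to judge it is missing); genomic match plus intact NS+VP is
ENDOGENOUS_INTACT; a bare genomic match is AMBIGUOUS; no genomic match is
EXTANT_CANDIDATE. Degraded outranks intact so mixed evidence reads as
degradation.

A PRS is a contamination suspect only when it is KNOWN_VIRUS_LIKE *and*
the known host lineage of its best reciprocal reference shares no taxon
with the dataset's host lineage at the configured rank — phylum by
default, moving to class when both sides are Chordata (so a
mammal-infecting virus in an amphibian dataset is incompatible despite the
shared phylum, while a plant dataset against an insect virus already fails
at the kingdom/phylum level). Suspects are tabulated separately from the
main summaries. The same rule applies to genome-derived PRSs, which also
covers contaminated genome assemblies (e.g. via infected parasite tissue).

## Stage 4 — SF3 helicase phylogenetics

The SF3 helicase domain is the most conserved parvoviral region and the
usual basis for genus-level phylogenetics. From each NS-bearing PRS
peptide the domain is extracted by local alignment against the reference
SF3 fragments, keeping at most 191 residues centred on the aligned core
(the window is configurable; narrower fragments are sometimes preferred
for more divergent sets). The score threshold is set where the expected
number of chance matches against the reference set is `1e-3`, mirroring
the pipeline-wide E-value philosophy.

Fragments plus references are aligned by single-pass progressive
alignment: 3-mer fractional-common-k-mer distances, a UPGMA guide tree,
and profile-profile alignment with sum-of-pairs BLOSUM62 scoring, affine
gaps and free end gaps. The alignment is deterministic under a fixed
input order and ungapping any row reproduces its input exactly. Iterative
refinement is deliberately omitted; alignment quality is acceptance-tested
by simulation (on substitution-only families the alignment is required to
be near-column-perfect) rather than by matching any particular aligner's
output.

Trees are built by neighbor joining on p-distances with pairwise deletion
(gap-affected columns are dropped per pair, not per alignment), negative
branch lengths clamped to zero. Support comes from column-resampling
bootstrap (500 replicates by default, seeded); inside replicates a pair
left with no comparable columns falls back to the matrix's largest
distance so every replicate yields a tree. The tree is rooted on the
outgroup helicase (a poxvirus D5 stand-in in the synthetic panel), with
supports kept attached to their edges, and the clade report lists every
maximal clade with support strictly above 0.70 whose leaves share one
host phylum and contain at least one PRS. Maximum-likelihood inference is
intentionally out of scope: the tree method is a consumer of the
pipeline, not its contribution, and NJ with bootstrap is deterministic
and fast at this scale; the alignment is exported in FASTA and relaxed
PHYLIP so an external ML tool can be swapped in.

## The synthetic benchmark

`generator_config()` fixes the study conditions; all randomness flows from
one seed. The default panel has 6 genera x 3 species (36 proteins) plus
one outgroup; NS proteins carry a conserved 191-aa SF3-like core that
mutates at half the rate of the rest of the protein, giving
intra-genus < inter-genus divergence (0.08 vs 0.40 per site). Eight hosts
span six phyla (two insects, a crustacean, a mammal, an amphibian, a
flatworm, a mollusc, a plant), each with a 50-transcript transcriptome and
a 2x30 kb genome — about 1 Mb of sequence, sized so the full pipeline
runs in about 1.5 minutes on one CPU.

Planted events (default mix): 10 EXTANT transcripts at 0.20-0.45 target
amino-acid divergence; 4 INTEGRATED_INTACT events planting an
ATG-anchored NS+VP cassette into the genome and a ~99%-identical copy
into a transcript; 6 INTEGRATED_DEGRADED genomic elements with premature
stops (2% per codon, rejection-sampled to at least one), a 50% chance of
a single-nucleotide deletion, TE insertions within the 500-nt flanks at
60% per side, and a 50% chance of an expressed transcript copy; 4
CONTAMINANT transcripts at ~96% identity to a panel virus whose host
lineage is incompatible with the dataset's host; and 5 decoy-derived
plants that must be rejected at reciprocal confirmation. Divergence is
realised by codon-level substitution with transition bias (kappa = 4,
stop-creating changes reverted for coding copies), so nucleotide and
amino-acid identity decouple realistically; the truth table records the
*realised* divergence, stop counts and TE placements per planted copy,
and `expected_labels()` maps those to the labels the classifier should
produce under its own documented rules.

What the generator does **not** emulate: assembly artifacts and chimeras,
sequencing error, real codon-usage and composition biases, repeat-rich
host backgrounds, segmental duplications of EVEs, and genuinely
novel-lineage PRSs below 30% identity (which sit at the edge of what
E-value-thresholded homology search can recover). Passing the planted
benchmark therefore demonstrates the pipeline's rules and statistics are
implemented correctly at realistic divergences, not that recall on heavily
diverged real fossils matches these numbers.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally and 1-based inclusive in
exported TSVs. Ordering of all outputs uses locale-independent radix
sorting, and doubles are written with 17 significant digits, so identical
inputs and configuration give byte-identical artifacts (the determinism
guarantee is itself under test). Ties among hits break by (E-value,
score, target id, query id, position). `N` scores 0 against every
nucleotide; `X` and `*` score as BLOSUM62 defines them. An empty FASTA is
an empty dataset, not an error; a forward E-value cutoff of 0 yields an
empty but clean run; sequences shorter than one codon refuse translation
explicitly. Problem sizes in the test suite (panel sizes, dataset
lengths, 100-instance oracle batches, 500-replicate bootstraps on 8-10
taxa) were chosen so the whole suite exercises every stage at full
fidelity in a few minutes on a single core.

## Known limitations

Profile-HMM detection (for remote homology) is not implemented; the
reciprocal step uses a user-supplied decoy set rather than a live
non-redundant database; E-values are deliberately conservative in the
deep tail; manual alignment curation, common before publication-grade
phylogenetics, is out of scope, as are integration dating and synteny
analysis.
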