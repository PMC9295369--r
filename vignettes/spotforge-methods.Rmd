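---
title: "spotforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotforge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotforge)
```

spotforge is the computational core of a spatial-transcriptomics
preprocessing workflow: it turns raw read pairs into a clean digital gene
expression (DGE) matrix with spatial structure, quality metrics and
registration to histology. This vignette explains the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Barcode flavors and read tagging

Array-based STS platforms place the spatial-unit barcode (CB) and the UMI
at platform-specific positions in Read1/Read2. spotforge describes this
declaratively: `cb=R1[1-16]; umi=R1[17-28]` means CB is Read1 positions
1–16 and the UMI positions 17–28, 1-based inclusive, with multiple
segments concatenated via `+`. Coordinates are converted exactly once at
parse time; everything downstream works with the parsed spans.

Two of the shipped presets deserve comment. Published coordinate tables
for Visium sometimes state the UMI as `R1[16-24]`, which overlaps the
16-nt spot barcode at position 16 and disagrees with the platform's known
12-nt UMI; similarly Slide-seq UMIs are sometimes given as `R2[15-23]`
although bead barcode and UMI are read together from Read1. We treat both
as transcription slips: the default `visium` preset uses
`cb=R1[1-16]; umi=R1[17-28]` and `slide_seq` uses
`cb=R1[1-14]; umi=R1[15-23]`, while the literal spellings remain
available as `visium_literal` and `slide_seq_literal` so either
convention can be reproduced byte-for-byte. Correctness is preferred over
literalism, with literalism one preset away.

The tagged-read sequence is always the Read2 (cDNA) mate. Reads too short
for a flavor span are flagged `short_read` and counted rather than
raising an error; a CB containing more than one `N` is flagged
`ambiguous_cb`, because downstream whitelist matching is exact-string and
such barcodes cannot be attributed reliably.

3′ trimming removes, in order, the longest terminal poly(A) run of at
least `min_polya_run` (default 6) exact `A`s, then any remaining suffix
equal to a ≥`min_adapter_overlap`-nt prefix of a user adapter. Exact
matching (no mismatch tolerance) keeps the operation deterministic and
the idempotence property testable; trimming never lengthens a read and
re-trimming a trimmed read is a no-op.

## Gene tagging and the multimapper rule

Alignments are tagged per overlapping gene on the *same strand* (sense
counting, matching the convention of the standard droplet-RNA tagging
tools): `EXONIC` if any aligned block overlaps any exon of that gene,
otherwise `INTRONIC`; with no same-strand gene overlap the alignment is
`INTERGENIC`. Interval arithmetic is delegated to
GenomicRanges/IRanges.

A read with several reported alignments is kept only when the evidence is
unambiguous: exactly one alignment carries a countable genic tag and
every other alignment is purely intergenic — then that alignment is kept
and flagged primary. A read whose countable alignment spans two genes, or
with two or more genic alignments, is discarded; a unique alignment
always passes through unchanged. "Countable" follows the run-mode: EXONIC
only by default, EXONIC ∪ INTRONIC when intronic counting is on. This
single definition reconciles the looser "genic" and stricter "exonic"
phrasings that float around descriptions of this rule: under exonic-only
counting an intronic alignment is neither countable (it cannot rescue the
read) nor intergenic (its presence still discards a multimapper). The
implementation is verified against an exhaustively enumerated oracle over
all multisets of up to four alignments in both counting modes.

## The DGE matrix

`count_dge` counts **distinct UMI strings** per (barcode, gene) over the
countable functions; intergenic reads contribute to per-barcode read
totals (the reads/UMI ratio should reflect sequencing effort, including
reads that map outside genes) but never to counts. UMI collapsing is
exact-string: no 1-edit merging, since edit-distance collapsing settings
differ between upstream tools and exact matching is deterministic and
auditable. Duplicate (cb, umi, gene) observations collapse regardless of
position. The "MAPQ = 0" convention of multimapper-inclusive counting is
modeled directly: with multimapper counting on, resolved multimappers
enter the stream; with it off, only `n_hits = 1` alignments do.

Barcode selection uses the provided whitelist verbatim, else ranks
barcodes by read count and keeps the top `n_beads`, with lexicographic
tie-breaking so the selection is reproducible. Barcode cleaning removes
(i) barcodes whose 3′ suffix of ≥4 nt equals a primer prefix and (ii)
barcodes sharing a ≥7 nt substring with a primer anywhere.

Replicate merging is pure set union on (cb, umi, gene): it is
commutative, associative and idempotent, and a random split of a read
stream merged back equals the unsplit matrix — the property the tests
exercise. Downsampling draws one random permutation per seed and takes
prefixes of length ⌊p·N⌋, which makes subsets exactly sized and nested,
so per-barcode UMI curves are monotone in the ratio by construction.
Saturation tables report median reads, UMIs, genes and reads/UMI per
spatial unit over the full-data barcode universe.

## Meshes and tissue detection

The mesh is a triangular lattice built exactly as described for in-silico
spot grids: a rectangular lattice with column spacing d and row spacing
√3·d, unioned with a copy translated by (d/2, √3·d/2). Every interior
center then has six equidistant neighbors at exactly d. The mesh is
anchored at the lower-left of the data bounding box and extended one
spacing beyond it — the anchor is otherwise arbitrary, and the extension
guarantees border units are assignable.

Hexagon meshes assign every unit to its nearest center (the Voronoi cell
of a triangular lattice is a hexagon), so aggregation conserves the grand
total exactly; circle meshes assign only units within
`spot_diameter_um/2` of a center, and a unit inside two overlapping
circles goes to the nearer center (ties to the lowest index) rather than
being double-counted or dropped.

Tissue detection marks units with UMI totals strictly above a user
threshold as candidates and returns the largest connected candidate
component. On regular arrays, adjacency is distance ≤ 1.3× the minimum
center distance: the factor must exceed 1 (the six hex neighbors) and
stay below √3 ≈ 1.73 (the second ring); 1.3 sits comfortably between.
Irregular arrays are first mapped onto a hexagonal mesh and adjacency
taken between neighboring cells. Ties between equal-size components go to
the larger summed UMI count, then to the component containing the
lexicographically smallest barcode — arbitrary but deterministic.

## Barcode-complexity QC

Spatial barcodes should be indistinguishable from uniform random
sequences; systematic structure indicates synthesis or sequencing
artifacts. Two per-barcode statistics are used: Shannon entropy of the
nucleotide composition, H = −Σ f(n) log₂ f(n) (N counts as a fifth
symbol so the length normalization stays exact; 0·log 0 = 0), and the
character length of the run-length encoding, count-then-symbol
(`AAACATTA` → `3A1C1A2T1A`, length 10; runs ≥10 take multi-digit counts,
the natural extension of the count-then-symbol scheme). The theoretical
baseline generates exactly as many uniform random barcodes as there are
real ones, from an explicit seed. Composition-by-quartile ranks barcodes
by read count and splits by *rank*, not value, so all four groups stay
non-empty under heavy ties; quartile 1 holds the lowest counts and
remainders go to the lower quartiles.

## Long-read signatures

Library-construction oligos (SMART handles, TSO, sequencing adapters) are
located on each long read by local Smith–Waterman alignment — delegated
to Biostrings' pairwise aligner with match 2, mismatch −2, gap open −3,
gap extend −1 (a length-L gap costs 3 + L), conventional values for
short-oligo detection and all CLI-exposed. A hit is accepted at ≥ 0.6 of
the block's perfect score; that default trades sensitivity against chance
hits and matters most for short blocks (an 18-nt block admits occasional
~15/18-identity chance matches in random sequence, a 25-nt block does
not), which is why realistic catalogs use full-length oligos.
Poly(T)/poly(A) blocks are detected as exact homopolymer runs ≥ 10 nt:
aligning against a homopolymer is degenerate under local alignment.
Repeated occurrences of one block are found by recursing into the
segments flanking each accepted hit, so TSO concatemers yield `TSO,TSO`
signatures. Overlaps of ≤ 2 nt between accepted hits are tolerated
(adapters frequently abut exactly); otherwise the higher-scoring hit
wins greedily. Reads whose accepted hits are mostly minus-strand are
reverse-complemented and re-annotated once so signatures are comparable
across orientations. Signatures order block names by read start;
`summarize_library` analyzes every k-th read (the long-read module is a
diagnostic, subsampling keeps it cheap) and reports signature counts,
the fraction matching the expected signature, and per-block
position/mismatch/deletion summaries.

## Image registration

Count data is rendered as a binary raster: Visium-style pucks as a
1000×1000 px image of a 6.5 mm square with each under-tissue unit drawn
as a 55 µm disk (8 px at that scale; even pixel diameters center the
disk between pixels so the drawn span equals the diameter), and
grid/bead data as count intensities scaled to a max of 255, binned to
1000×1000 and binarized. The published description of that binarization
— "a binary filter between 190 and 200" — is ambiguous (band? threshold
range?); a pure band mask turns uniform high-intensity fields into empty
masks, so the default searches the threshold t ∈ [190, 200] that
maximizes the largest connected foreground component, and the literal
band mask remains available as `mode = "band"`.

H&E images are converted to luminance grayscale and thresholded by Otsu's
between-class-variance criterion (EBImage); darker-than-threshold pixels
are foreground since H&E tissue is dark on a light background.

Matching maximizes zero-normalized cross-correlation (per-offset Pearson;
on binary images this is invariant to swapping foreground and background
in both images) over a grid of independent x/y scales, from one-third of
the reference size up to the full size. The correlation map is computed
exactly via an FFT cross term plus integral-image window statistics — no
installed R package provides an OpenCV-style `matchTemplate`, so this
primitive is implemented here and verified per-offset against direct
Pearson correlation in the tests. The template's native size is always
evaluated when it lies inside the scale range, so an exact crop
self-matches with score 1 at the exact offset. Degenerate (zero-variance)
windows score 0. Ties break toward the lowest (y, x, scale) so results
are deterministic. Image convention throughout: row-major matrices,
origin top-left, y down, 0-based offsets.

## Synthetic data and what the tests show

Every generator takes an explicit seed, sets the RNG locally and restores
the caller's state, so fixtures are bit-reproducible and independent.
The generators emulate the *structural* properties the pipeline contracts
depend on — flavor-consistent read layouts, per-pair UMI pools (so
saturation has a closed-form ceiling), planted hex-lattice tissue blobs
with strictly separated UMI levels, reads concatenated from catalog
blocks, image pairs embedding a resized template at a known placement.
They do not model expression-level biology (no gene-length, GC or
capture-efficiency effects), sequencing-quality profiles, or barcode
synthesis error structure; green tests certify the algorithmic contracts
(exact recovery, conservation, oracle agreement), not biological
realism on real libraries.

Problem sizes were chosen so the whole suite runs in a few minutes on one
CPU: 20×20 meshes and pucks, 50×20 planted DGEs, 200 random
alignment-oracle pairs (15-nt blocks vs 200-nt reads), 40–50 long reads
per composition, 96–112 px image pairs with 20 seeded placements and a
0.05 scale step. At these sizes every acceptance property is exact or
holds with margin; the acceptance script reports the measured values.

## Known limitations

* Barcode correction (quality-aware or edit-distance) is out of scope;
  whitelist matching is exact.
* The circle-mesh overlap policy (nearest center) is a convention;
  platforms with diameter > spacing may define capture differently.
* Registration is translation + independent x/y scaling only — no
  rotation, shear or non-rigid deformation, and no fiducial detection.
* The long-read module reports signatures; it does not error-correct or
  build consensus sequences.
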