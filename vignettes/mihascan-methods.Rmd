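---
title: "Modelling the minor histocompatibility antigen landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the minor histocompatibility antigen landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihascan)
```

## The problem

After HLA-matched allogeneic stem-cell transplantation, donor T cells
encounter recipient peptides they were never tolerised against:
peptides encoded by non-HLA polymorphisms where the recipient carries
an allele the donor lacks. These minor histocompatibility antigens
(MiHAs) mediate the graft-versus-leukemia effect and graft-versus-host
disease, and common ones are candidate targets for off-the-shelf
post-transplant T-cell therapy. `mihascan` quantifies this landscape in
three stages: (i) construct both individuals' variant-aware diploid
proteomes and the donor-subtracted unique recipient peptidome, (ii)
model the probability that a given peptide is mismatched in a random
pair as a function of its encoding-allele frequency, and (iii) restrict
to peptides predicted to bind MHC class I. Immunogenicity prediction —
whether a presented mismatched peptide actually elicits a response — is
deliberately out of scope: no current model predicts it reliably, so
the pipeline stops at the presented-mismatch stage.

## Proteome construction

Each transcript is a spliced coding sequence with genomic exon
coordinates and strand. VCF positions are 1-based; all internal
arithmetic is 0-based half-open, converted exactly once at the reader
boundary. A variant projects onto a transcript only if its REF span
lies within a single exon — variants straddling exon boundaries are
dropped at read time (they are rare in real coding data and their
effect is not well defined without full splice modelling). On
minus-strand transcripts both alleles are reverse-complemented during
projection.

Per haplotype, alleles are applied right-to-left in CDS coordinates so
upstream offsets stay valid; overlapping REF spans on one haplotype
keep the downstream-most allele (a deterministic tie-break, logged as a
conflict). Translation uses the standard genetic code, stops at the
first in-frame stop, and discards a trailing partial codon. Decisions
where the underlying biology is ambiguous:

* **Stop-loss alleles** read through to the end of the provided CDS and
  are flagged; 3′UTR read-through is not modelled because UTR sequence
  is not part of the input contract.
* **Start-codon disruption** yields an empty haplotype protein, with no
  downstream-ATG rescue.
* **Frameshifts** translate in the new frame to the first stop — the
  premature-truncation behaviour that dominates real loss-of-function
  variation.
* **Selenocysteine** is not modelled; transcripts with internal stop
  codons are excluded on input.

The builder is verified against an independent oracle that rebuilds the
full genomic sequence, applies variants by genomic position, re-splices
with shifted exon boundaries and translates — a deliberately different
computational path.

## URPs and their provenance

Peptidomes are the sets of distinct k-mers (k = 9 by default, the
dominant class I ligand length; all window arithmetic is k-generic)
over both haplotypes of all transcripts. A unique recipient peptide
(URP) is a string present anywhere in the recipient's peptidome and
nowhere in the donor's. Distinct-string semantics apply throughout: the
same peptide arising from two transcripts is one URP with merged
provenance.

Causal attribution walks each recipient occurrence's applied-variant
intervals: alleles whose altered residues overlap the window, minus
alleles the donor shares. Classes follow the genetic mechanism: one
causal missense SNV (`single_nsSNP`), several within one window
(`adjacent_nsSNPs` — "adjacent" is operationalised as co-occurrence in
one k-window, since no distance convention exists), in-frame indels,
recipient frameshifts, and reference-encoded peptides that the donor
lost by being homozygous for a truncating allele
(`homozygous_frameshift_donor`, `homozygous_nonsense_donor`). A
reference-encoded peptide opposite a donor-homozygous *missense* allele
is also a nsSNP-class URP; its encoding allele is the reference allele,
so its frequency is 1 − f(alt). Anything genuinely multi-causal — for
example a shared allele whose donor copy is disrupted by a second
polymorphism — is `combination`, never dropped. Indel provenance
intervals include one flanking codon on each side so junction peptides
are always attributed; over-covering is harmless because provenance is
only consulted for peptides already proven unique by set subtraction.

For multi-variant URPs the encoding-allele frequency is the *minimum*
causal-allele frequency — conservative for the mismatch probability,
since the rarest required allele bounds the probability that the whole
configuration occurs.

## The mismatch-probability model

For a peptide encoded by an allele at population frequency $f$, under
Hardy–Weinberg equilibrium,

$$P_{mm}(f) = f\,(1-f)^2\,(2-f) = \bigl(1-(1-f)^2\bigr)(1-f)^2$$

is the probability that the recipient carries the allele and an
unrelated donor does not. For siblings, enumerating parental genotypes
and Mendelian transmissions gives

$$P_{mm}^{sib}(f) = (1-f)^2\, f\,(4-f)/4 .$$

Both formulas are embodied in the test-suite as brute-force
enumerations (the 3×3 HWE genotype-pair table; the parental-genotype ×
transmission table) and as vectorised Monte-Carlo simulations, which
recover them within three standard errors at 200,000 replicates. Useful
facts the package computes rather than hard-codes:

* the unrelated maximum is exactly $1/4$ at $f^\ast = 1 - 1/\sqrt 2
  \approx 0.293$; the sibling maximum $\approx 0.136$ at
  $f^\ast = (7-\sqrt{33})/4 \approx 0.314$ (numeric optimisation,
  tolerance $10^{-12}$, cross-checked against the closed forms);
* the frequency window above a threshold comes from bisection on each
  side of the argmax; for the unrelated model the closed form
  $(1-f)^2 = \bigl(1 \pm \sqrt{1-4t}\bigr)/2$ is used as a test oracle.
  At $t = 0.2$ the window is $(0.15, 0.47)$; at $t = 0.1$ the lower
  bound is $0.06$ and the computed upper root is $0.6643$;
* the probability of observing a peptide in at least one of $n$
  independent pairs is $1-(1-p)^n$ — above 99.99 % at $p = 0.1$,
  $n = 100$, which is why a 100-pair cohort saturates the
  therapeutically relevant URP space;
* the expected sibling-vs-unrelated yield ratio is
  $\int P_{mm}\varphi \,/ \int P_{mm}^{sib}\varphi$ over a frequency
  spectrum $\varphi$ (adaptive quadrature on $(10^{-12}, 1-10^{-12})$,
  relative tolerance $10^{-10}$). For the uniform spectrum the
  polynomials integrate to $2/15$ and $3/40$, ratio $16/9 \approx 1.8$.
  The pointwise ratio is $4(2-f)/(4-f)$, decreasing from 2 at $f \to 0$
  to $4/3$ at $f \to 1$.

Both formulas treat loci independently (no linkage disequilibrium) and
assume random mating; the sibling model uses one transmission draw per
parent per chromosome with no recombination, which is sufficient
because the formula is per-locus.

## Binding calibration and co-dominance

The bundled predictor is an additive position-specific scoring matrix;
published neural-network predictors are pluggable through the same
peptide-to-score interface (score tables or matrices), and are not
re-implemented. Thresholds are *percentile-calibrated*: the strong and
weak cutoffs are the scores of the $\lceil pN\rceil$-th highest of $N$
background peptides sampled uniformly from the reference proteome
(defaults $p = 0.005$ and $0.02$). A peptide tied with the cutoff is a
binder; when a tie block straddles the rank, the cutoff moves up to the
next distinct score so the at-or-above background fraction never
exceeds $p + 1/N$. Consensus filtering intersects the calls of two
predictors at a chosen stringency, and weak binders include strong by
convention.

An nsSNP is *co-dominant* when peptides from both alleles pass the
binding level and *dominant* when only one side passes. Because
substitutions to arginine or lysine alter proteasomal cleavage and
inflate one-sided calls, the statistic can exclude R/K-containing
peptides before counting; a zero dominant count reports an infinity
marker rather than failing.

## The synthetic-data generator

The generator's defaults emulate the statistical structure of a phased
population cohort at desk scale: 30 transcripts of 100–300 codons (1–3
exons, random strand, uniform sense-codon usage), 150 coding variants,
a cohort of 200 samples (100 disjoint virtual pairs — the pairing
design of a typical population-scale analysis), and a **uniform**
allele-frequency spectrum. The variant-type mixture (85 % missense,
3 % linked adjacent-missense pairs, 4 % in-frame indel, 5 % frameshift,
3 % nonsense) keeps nsSNPs dominant, as in real coding variation, while
exercising every classifier branch. A truncated-1/f spectrum is
available where a more realistic site-frequency shape matters; the
uniform default is what the fold-reduction analysis integrates over, so
analytic expectation and simulation stay directly comparable.

Missense draws are re-sampled until the substitution is truly
nonsynonymous, so generator labels are exact ground truth for
classifier tests. Adjacent-missense draws emit a perfectly linked pair
(one inheritance draw) so adjacent-nsSNP URPs actually co-occur on a
haplotype — with independent sampling they would appear only at rate
f². Genotypes are independent Bernoulli(f) per haplotype (HWE by
construction); sibling pairs draw two HWE parents and transmit one
haplotype per parent per chromosome. Everything is a pure function of
the config seed, and every generated file round-trips through the
package's readers.

What the generator does *not* emulate: linkage disequilibrium between
sites, realistic codon usage and gene structure, population structure,
genotyping error, and any correlation between allele frequency and
variant effect. Passing tests therefore validate the *mechanism* —
projection, translation, subtraction, counting, calibration — and the
model's internal consistency, not the absolute URP counts of a real
exome, which depend on the real site-frequency spectrum and transcript
complement and are far larger.

## Problem sizes and numerical conventions

The test-suite runs everything at deliberately small scale, chosen so
statistical checks retain power: oracle equivalence on ~100+ random
haplotype proteomes (transcripts of 30–90 codons); Monte-Carlo formula
recovery at 200,000 pairs per frequency point (binomial SE ≈ 0.001,
3-SE check); the fold-reduction simulation on 12 transcripts, 250
missense variants, 40 unrelated + 40 sibling full-pipeline pairs,
compared to 16/9 within three delta-method standard errors; calibration
contracts on 10,000-peptide backgrounds. Root finding and optimisation
use tolerances of 1e-12; quadrature 1e-10 relative. Degenerate inputs
are defined, not crashed on: empty URP sets profile to zeros with a
warning, identical genomes give zero URPs, an all-co-dominant cohort
reports an infinite ratio, and empty annotation files read as empty
transcript lists.

## Known limitations

Only normal-reading-frame 9-mers from annotated coding transcripts are
considered: 10/11-mers, alternative reading frames, non-coding and
proteasome-spliced peptides are outside the model, as are structural
variants, sex chromosomes, and splice-affecting variation. The binding
stand-in is a generic PSSM — adequate for studying calibration and
consensus logic, not a replacement for trained predictors. Mismatch
probabilities assume HWE and locus independence; strong LD between
URP-coding SNPs would correlate mismatch events that the model treats
as independent.
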