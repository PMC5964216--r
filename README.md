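# punctaflux

Per-neuron quantification of autophagy state from multi-channel fluorescence
micrographs, and classification of the observed changes into autophagy
dysfunction modes.

## The problem

Autophagy delivers cytoplasmic cargo to lysosomes through LC3-II-decorated
autophagosomes; cargo-adaptor proteins such as optineurin (OPTN) link cargo
to LC3. In tissue sections, autophagy can only be assessed statically, from
immunofluorescence: the diffuse expression of LC3 and OPTN, their punctate
forms (bright, roughly circular dots of 0.5–2.0 µm, the size range of
autophagosomes), and the fraction of puncta in which the two markers
colocalize. Different failure modes of the pathway — impaired induction,
impaired OPTN–LC3 binding, failed autophagosome–lysosome fusion, exhaustion
of either component — leave distinct direction signatures across those
endpoints. `punctaflux` implements the full measurement-and-inference chain
for this assay, and a synthetic confocal-field generator with exact ground
truth so that every stage can be validated quantitatively.

## What the pipeline computes

For each neuron (segmented from a cell-marker channel):

* **Expression** — background-corrected mean intensity of the OPTN and LC3
  channels over the soma ROI, reported relative to the control group
  (control = 100%).
* **Puncta** — multi-scale Laplacian-of-Gaussian detection of bright
  circular spots; a spot is kept only if its estimated full-width-at-half-
  maximum diameter lies in 0.5–2.0 µm, it stands out from a median-filtered
  local background, and its response lobe is compact and isotropic.
* **Colocalization** — one-to-one greedy matching of OPTN and LC3 puncta by
  centroid distance (≤ 0.5 µm); per cell,
  `% colocalized = 100 · n_matched / n_OPTN` and `100 · n_matched / n_LC3`.
* **Group statistics** — D'Agostino–Pearson K² normality screen, then
  Kruskal–Wallis omnibus across stages and Dunn's post-hoc versus control
  (Bonferroni over the vs-control family, α = 0.05), yielding a signed
  `up` / `down` / `no_change` call per endpoint and stage.
* **Classification** — the seven-slot direction pattern (expression ×2,
  puncta ×3, % colocalized ×2) is scored against six decision-table
  templates of dysfunction modes; the verdict matrix marks each
  category/evidence block `X` (full agreement), `/` (partial), or blank
  (contradicted).

## Worked example

The `analysis/` scripts run a complete study on synthetic data: simulate a
four-stage cohort (control, 24 h, 5 d, end-stage) for one brainstem region
under an *impaired OPTN–LC3 interaction* scenario, measure every neuron,
test every endpoint, and classify each stage.

```sh
Rscript analysis/01_simulate_fields.R
Rscript analysis/02_measure_cells.R
Rscript analysis/03_group_statistics.R
Rscript analysis/04_classify_dysfunction.R
Rscript analysis/05_validation_studies.R
```

`02_measure_cells.R` prints the per-stage mean detected counts per neuron:

```
     group n_adaptor n_autophagosome  n_coloc
       24h  12.11667        6.533333 2.166667
        5d  12.00000        5.750000 1.900000
   control   9.35000        7.316667 3.383333
 end_stage  11.65000        5.933333 1.916667
```

OPTN puncta rise while colocalized puncta fall in every treated stage — the
interaction-failure signature. `03_group_statistics.R` turns these into
calls (e.g. `pct_coloc_adaptor / 24h / down, p_adj = 5.4e-08`), and
`04_classify_dysfunction.R` prints the verdict matrix, in which
`impaired-interaction` carries `X` in all three evidence blocks of every
treated stage and is the matched category throughout.

`05_validation_studies.R` quantifies the measurement chain against ground
truth: detection F1 0.975 at a 0.25 µm matching radius, colocalized-fraction
recovery within ~1 percentage point, null false-call rate 4.4% at a nominal
5%, and 100% power for a one-SD location shift.

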