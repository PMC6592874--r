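# ieegbids

Read, write, validate and simulate **iEEG-BIDS** datasets in R.

Intracranial electroencephalography (iEEG) — electrocorticography from
subdural grids and strips (ECoG), stereotactic depth recordings (sEEG), and
deep-brain-stimulation leads (DBS) — is increasingly shared under the Brain
Imaging Data Structure (BIDS): a fixed folder hierarchy
(`sub-<label>/[ses-<label>/]ieeg/`), entity-based filenames
(`sub-01_task-motor_run-01_ieeg.edf`), and sidecar metadata files. This
package is a self-contained toolkit for that standard, aimed at labs curating
iEEG recordings for sharing and at tool authors who need a deterministic
validator and a reproducible test corpus:

* **Filename grammar** — `parse_bids_path()` / `build_bids_path()` parse and
  render entity sets (`sub`, `ses`, `task`, `acq`, `run`, `space`) with a
  guaranteed round trip; `enumerate_dataset()` classifies a whole tree;
  `resolve_sidecars()` implements sidecar inheritance.
* **Signal formats** — bit-exact readers/writers for the two *compliant*
  iEEG-BIDS formats: European Data Format (`read_edf()` / `write_edf()`,
  16-bit samples with per-channel sampling rates, physical/digital scaling
  `P = pmin + (D − dmin)(pmax − pmin)/(dmax − dmin)`) and the BrainVision
  Core triplet (`read_brainvision()` / `write_brainvision()`, `INT_16` or
  bit-exact `IEEE_FLOAT_32`). The three *unofficially supported* formats
  (`.nwb`, `.set`, `.mefd`) are recognized by tier, never parsed.
* **Sidecar metadata** — typed loaders/writers for `_ieeg.json`,
  `_channels.tsv`, `_electrodes.tsv`, `_coordsystem.json`, `_events.tsv`,
  with `"n/a"` missing-value semantics and SI unit normalization
  (`normalize_unit("uV")` → `"µV"`, micro sign U+00B5).
* **Dataset validator** — `validate_dataset()` produces a deterministic
  report of coded issues (`E_*` errors, `W_*` warnings), including
  cross-file rules: electrode tables must pair with coordinate systems,
  `IntendedFor` images must exist, channel tables must match the data
  file's channel count, order and rates. Unofficial formats pass with a
  warning.
* **Synthetic corpus** — `generate_dataset()` emits five seeded archetype
  datasets (auditory filtered speech, motor movement, visual stimulus,
  seizure sEEG with two sampling rates, multimodal ECoG+MRI), byte-identical
  across runs; `corrupt_dataset()` injects exactly one defect per validator
  error code for negative testing.

## Worked example

```r
library(ieegbids)

root <- file.path(tempdir(), "demo")
generate_dataset("seizure_seeg", root, seed = 42)

rec <- read_edf(list.files(root, pattern = "_ieeg\\.edf$",
                           recursive = TRUE, full.names = TRUE)[1])
rec
#> <ieeg_recording> 12 channel(s), 8 s, format=edf (int16)
#>   rates (Hz): 256, 512
#>   channels:   A1, A2, A3, A4, A5, A6, B1, B2, ...

validate_dataset(root)
#> iEEG-BIDS validation of /tmp/.../demo: VALID (0 error(s), 0 warning(s), 8 file(s))
#>   no issues

corrupt_dataset(root, "E_COORDSYS_MISSING")
glance(validate_dataset(root))
#> # A tibble: 1 × 4
#>   valid n_errors n_warnings n_files
#>   <lgl>    <int>      <int>   <int>
#> 1 FALSE        1          0       7
```

The twelve channels are two sEEG depth leads (A, B) sampled at 512 Hz and
256 Hz — EDF's per-channel-rate feature — and the report shows the dataset
flipping to invalid once its electrode positions lose their paired
coordinate system.

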