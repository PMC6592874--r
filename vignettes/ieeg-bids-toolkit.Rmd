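---
title: "Validating and simulating iEEG-BIDS datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and simulating iEEG-BIDS datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegbids)
```

## The problem this package addresses

Intracranial EEG is recorded in hospitals and labs with heterogeneous
acquisition systems, file formats and naming habits. The iEEG extension of
the Brain Imaging Data Structure standardizes three things: a folder/file
naming grammar, a small set of accepted signal formats, and sidecar
metadata that makes a recording interpretable without the original lab
notebook. `ieegbids` implements all three as testable machinery: parsers
and writers, a rule-based validator, and a seeded generator of complete
example datasets.

Two domain distinctions drive the design:

* **Channels vs. electrodes.** A *channel* is the time series produced by
  one analog-digital converter of the recording system; it lives in the
  data file and in `_channels.tsv` (type, units, hardware filter
  settings, sampling rate). An *electrode* is a physical contact with
  tissue; it lives in `_electrodes.tsv` with spatial coordinates. The
  validator ties the two together: channel tables must match the data
  file channel-for-channel and in order (channel order is meaningful in
  binary payloads, so a same-set/different-order table gets its own code,
  `E_CHANNEL_ORDER`), while an intracranial channel with no located
  electrode is only a warning — and a *spare* electrode that was never
  recorded from is fine.
* **Two format tiers.** EDF and the BrainVision Core triplet are
  *compliant*: the package reads and writes them, and content rules run
  against their payloads. `.nwb`, `.set` and `.mefd` are *unofficially
  supported*: they pass validation with `W_UNOFFICIAL_FORMAT`, their
  payloads are never parsed, and content checks degrade to `W_UNCHECKED`.

## Signal formats and numerical choices

**EDF.** Classic EDF stores 16-bit two's-complement samples; each channel
carries a linear map `(physical_min, physical_max, digital_min,
digital_max)`, and physical values are reconstructed as
`P = pmin + (D − dmin)(pmax − pmin)/(dmax − dmin)`. The writer fixes the
record duration at 1 s so samples-per-record equals the per-channel
sampling rate — this is how EDF expresses *variable rates per channel*,
which the seizure archetype exercises with 512 Hz and 256 Hz depth leads.
Consequences of that choice: rates must be whole numbers of samples per
second and durations whole seconds. Writing quantizes (half-step rounding,
error at most one step of `(pmax − pmin)/65535`); reading back and
re-writing reproduces the byte stream exactly, which the tests assert
against an independently coded brute-force scaler. EDF+ annotation
channels and discontinuous files are out of scope; a continuous EDF+ file
without annotation channels still reads.

**BrainVision.** The `.vhdr`/`.vmrk` text files are parsed as INI
sections (UTF-8 with a Latin-1 fallback for legacy headers; always
written UTF-8); `.eeg` is raw little-endian binary, multiplexed
orientation only (`VECTORIZED` is rejected rather than half-supported).
Stored values are `physical / resolution` per channel. With
`IEEE_FLOAT_32` and the default resolution of 1 the roundtrip is
bit-exact — `snap_float32()` is provided to pre-round doubles to single
precision so a write/read cycle is the identity. With `INT_16` the
roundtrip error is bounded by half the resolution (0.05 µV at the 0.1 µV
default). The sampling rate derives from the microsecond sampling
interval (`fs = 1e6 / interval`).

**Units.** Physical units are SI symbols with one optional prefix; micro
is the micro sign U+00B5. `normalize_unit()` rewrites Greek mu (U+03BC)
and the ASCII `u` fallback, plus `Ohm`/`degC` spellings, and is
idempotent. Unit strings that fail normalization are warnings, not
errors: they degrade interpretability but not structure.

## The validator

`validate_dataset()` runs name/tree checks, per-file sidecar checks,
format-tier checks, then cross-file checks, and sorts issues by
`(path, code)` so byte-identical trees produce byte-identical reports.
Severity is fixed per code in `issue_registry()`. Where the standard
leaves severity open, the package's rule is: *errors* mark datasets an
analyst cannot safely interpret (missing coordinate system, dangling
`IntendedFor`, channel-count mismatch, missing required keys/columns,
missing `_ieeg.json`); *warnings* mark reduced quality (unknown
vocabulary entries, unlocated channels, unknown JSON keys — preserved
verbatim for forward compatibility — and unofficial formats). A dataset
must contain at least one iEEG recording per subject: this package
validates the iEEG extension specifically, so an anatomy-only subject is
an error. Electrodes localized in multiple spaces pair with coordinate
systems space-by-space via the `space` entity; `pixels` units are only
legal for 2-D electrode tables (a table is uniformly 2-D, `z` all
`"n/a"`, or uniformly 3-D — mixing is an error because the standard
gives mixing no semantics).

Session folders and the `ses-` entity are jointly optional but must
agree when present. Entity labels are restricted to `[A-Za-z0-9]+`
(hyphen and underscore are the grammar's delimiters); matching is
case-sensitive so behavior does not depend on the filesystem. `run`
renders zero-padded to two digits but any parsed width is preserved, so
parse∘build is the identity on rendered names.

## The synthetic corpus

`generate_dataset()` emulates the five study archetypes that the iEEG
community has used as public examples: auditory filtered speech (8-contact
ECoG grid, BrainVision int16, a `/stimuli/` folder with generated WAV
tones referenced from `_events.tsv`), motor movement (two subjects, grid +
strip + trigger channel, EDF), visual stimulus (BrainVision float32 at
500 Hz with 2-D pixel electrode coordinates), seizure sEEG (two depth
leads at two EDF sampling rates, a session layer), and multimodal
ECoG+MRI (an 8×8×8-voxel NIfTI-1 volume targeted by `IntendedFor`, with
an `"Other"` coordinate system described relative to that image).

Signal content is *synthetic by construction*: a 1/f-weighted sum of
sinusoids with seeded random phases, a mains component at the archetype's
power-line frequency (50 or 60 Hz, verified in tests by a periodogram
check on the exact FFT bin), event-locked amplitude bumps, and white
noise, quantized to 0.1 µV. Scale is deliberately tiny — one or two
subjects, at most 13 channels, 6–8 s at up to 512 Hz — so the entire
corpus (all five archetypes plus the 22-operator corruption sweep)
regenerates in seconds. What passing tests therefore show is that the
*machinery* is correct: grammar, scaling, cross-file rules, determinism.
They do not show robustness to the pathologies of real exported data —
vendor-dialect EDF headers, inconsistent clock drift, electrode tables
hand-edited in spreadsheets — beyond the specific defect classes the
corruption operators model.

Determinism is a contract, not an accident: JSON keys are written in a
fixed canonical order, numbers in plain notation without trailing zeros,
newlines are `"\n"`, the NIfTI volume is gzipped with a zero modification
time, and every random draw flows from the user's seed through an
RNG-state-restoring wrapper. Generating the same archetype twice with the
same seed yields byte-identical trees.

`corrupt_dataset()` provides one operator per error code. Operators that
must rename entity-bearing files (dropping `task-` or `ses-`) rename
*every* file of the affected recording so sidecar resolution stays intact
and exactly the targeted code fires — the one-defect/one-code property
the test suite asserts over the whole registry.

## Open choices made here

The standard's prose does not pin down every mandatory field; this
package chooses once and documents: iEEG data files require `subject` and
`task`; `_ieeg.json` requires `TaskName`, `SamplingFrequency`,
`PowerLineFrequency` (restricted to 50, 60 or `"n/a"` — physical mains
frequencies, anything else is a data-entry error), `SoftwareFilters` and
`iEEGReference` (the referencing scheme applied before digitization);
`_channels.tsv` leads with `name`, `type`, `units` in that order (order
deviations warn, absences error); `"n/a"` is the sole missing-value
token in TSVs. When more than one coordinate space is present the
`space` entity disambiguates the pairs. These defaults follow the
broader BIDS ecosystem where it is explicit and are centralized in the
package so a future revision touches one registry, not scattered logic.

## Limitations

No NWB/EEGLAB/MEF3 payload I/O (recognition only, by design); no EDF+
annotations; no HED event vocabularies; no electrode localization from
imaging; no derivatives trees. The validator checks structure and
metadata consistency, not scientific plausibility of the signals.
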