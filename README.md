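# xdfstream

Synchronized multi-sensor streaming, XDF recording and post hoc alignment —
a desk-scale, fully testable model of a Lab Streaming Layer (LSL) style
acquisition stack for multimodal physiological and sensor data (mHealth,
mobile EEG, motion capture).

## The problem and the model

Every device in a multi-sensor setup timestamps samples with its own clock;
clocks differ by an arbitrary offset and drift apart at tens of parts per
million. `xdfstream` implements the standard remedy end to end:

* **Transport** — an in-process registry of stream outlets/inlets with
  ordered, lossless delivery (`StreamRegistry`, `stream_info()`).
* **Clock synchronization** — repeated NTP-style round trips between the
  recorder's master clock and each source clock. One probe estimates the
  source−consumer difference as θ = ((t₁−t₀) + (t₂−t₃))/2; a measurement is
  the median of 5 probes, and the recorded offset (consumer − source) makes
  `corrected = raw + offset`. Offsets are measured at start and every 5 s
  (`measure_offset()`, `offset_at()`).
* **Recording** — a fault-tolerant recorder that buffers each stream for
  500 ms, writes buffered samples as XDF chunks with write-through, records
  offsets every 5 s, and finalizes per-stream footers (sample count,
  first/last timestamp, measured rate (N−1)/(t_N−t₁), offset series). An
  abnormal termination loses at most 500 ms of samples and leaves a loadable
  file without footers (`RecordingSession`, `XdfWriter`).
* **File format** — bit-exact writer and reader for the XDF 1.0 container,
  including truncated and footerless files (`read_xdf()`, `validate_xdf()`).
* **Post hoc synchronization** — offset application, least-squares timestamp
  dejittering, effective-rate estimation, gap detection, and resampling of
  several streams onto a common grid for cross-device comparison
  (`synchronize()`, `dejitter()`, `effective_srate()`, `detect_gaps()`,
  `align_streams()`).
* **Virtual devices** — sine generators and motion-sensor sources on clocks
  with configurable offset/drift/jitter, load-dependent effective sampling
  rates, and fault injection (pause, terminate), driving six reproducible
  validation scenarios (`run_s1a()`, `run_s1b()`, `run_s2()`, `run_s3()`,
  `run_fault()`).

## Worked example

Two simulated phones run a 10-channel sine generator (nominal 250 Hz,
achieving 203 and 213 Hz effectively) on clocks that are seconds apart and
drift in opposite directions; one recorder captures both streams, and the
loader synchronizes and aligns them:

```r
library(xdfstream)
r <- run_s1a(duration = 60, seed = 1)
print(r)
#> <scenario_report> s1a (seed 1, 60 s simulated): PASS
#>   channel_correlations: 0.999998, 0.999993, 0.999985, 0.999973, 0.999958, 0.999939, 0.999917, 0.999887, 0.999858, 0.999823
#>   min_correlation: 0.999823
#>   raw_phase_drift_4s: 0.183707
#>   effective_srates: 203.026, 213.008
```

Reading the numbers: before alignment the two raw streams drift apart by
0.18 s over just 4 s of samples (`raw_phase_drift_4s`) — the sampling-rate
mismatch that makes naive index-wise comparison meaningless. After applying
the recorded clock offsets and resampling both streams onto a common 100 Hz
grid, every one of the ten matched sine channels correlates above 0.999
(`min_correlation`), and the footer statistics recover the configured
effective rates to within a few hundredths of a hertz.

The same machinery handles degraded recordings:

```r
k <- run_fault("kill", duration = 40, seed = 7)
print(k)
#> <scenario_report> fault_kill (seed 7, 40 s simulated): PASS
#>   kill_time: 18.9889
#>   samples_pushed: 1899
#>   samples_recovered: 1850
#>   trailing_loss_s: 0.489928
```

The recorder was killed mid-run at t = 19 s: the file has no footer but
loads, and the 49 trailing samples lost correspond to 0.49 s — inside the
500 ms bound guaranteed by the 500 ms flush interval.

A thin CLI over the same functions lives at `inst/cli/xdfstream.R`
(`scenario`, `inspect`, `sync` subcommands).

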