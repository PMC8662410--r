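---
title: "Synchronized multi-sensor recording: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronized multi-sensor recording: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdfstream)
```

## The problem

When several devices — phones streaming their built-in motion sensors, a
signal generator, an EEG amplifier — record simultaneously, each device
timestamps its samples with its own internal clock. Those clocks start at
arbitrary epochs and run at slightly different speeds, so streams cannot be
related to each other directly: an offset of seconds and a drift of tens of
parts per million (ppm) accumulate into errors that make multimodal analysis
meaningless. The standard remedy, as implemented by the Lab Streaming Layer
ecosystem, is (a) to measure the offset between every source clock and one
master clock — the recorder's — repeatedly during the recording, (b) to store
raw timestamps *and* the measured offsets in the file, and (c) to map
timestamps onto the master clock after the fact.

`xdfstream` implements that whole stack at desk scale: an in-process
transport, the offset estimator, a fault-tolerant chunked recorder writing
XDF files, a reader that copes with killed recordings, post hoc
synchronization/dejittering/alignment, and virtual devices whose clocks
drift and jitter by construction so every claim can be checked against known
ground truth.

## Clock model

A `VirtualClock` maps true time $\tau$ (seconds) to device time

$$ c(\tau) = \tau\,(1 + d\cdot 10^{-6}) + o_0 + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma_j^2), $$

with initial offset $o_0$ (s), drift $d$ (ppm) and per-read jitter
$\sigma_j$ (s). Reads within an ascending query are clamped non-decreasing,
so jitter never makes a clock run backwards. Typical simulated devices use
$|o_0|$ up to a few seconds, $|d| \le 50$ ppm and $\sigma_j \approx 0.2$ ms
— values in the range consumer hardware exhibits. Recorder hosts are
modelled with millisecond-scale $o_0$ and small drift, as NTP-disciplined
computers and phones are; source devices may be seconds off, since that is
exactly what synchronization corrects within a file.

## Offset estimation

One measurement consists of $n$ round-trip probes (default 5, spaced 10 ms).
A probe records $t_0$ (consumer send), $t_1$ (source receive), $t_2$ (source
reply) and $t_3$ (consumer receive), and estimates the source-minus-consumer
difference by the classical NTP formula

$$ \theta = \tfrac{1}{2}\left[(t_1 - t_0) + (t_2 - t_3)\right], $$

which is exact when the outbound and return delays are equal. The
measurement combines probes with a median, so a probe that hits an
asymmetric delay spike is discarded rather than averaged in; the number of
round trips behind one recorded offset is not prescribed by the ecosystem
being modelled, and median-of-5 is this package's choice, asserted by tests.
The recorded offset is $-\operatorname{median}(\theta)$, fixing the sign
convention used everywhere in the package:

$$ \text{offset} = \text{consumer} - \text{source}, \qquad
   \text{corrected} = \text{raw} + \text{offset}. $$

Offsets are measured immediately when a recording starts (so even very short
files are synchronizable) and every `offset_interval` = 5 s thereafter, each
result written both as a ClockOffset chunk and into the stream's footer.
If a source has terminated, the probe times out, that cycle is skipped and
the series collected so far is retained — synchronization degrades, the
recording does not fail.

Post hoc, `offset_at()` interpolates the recorded series piecewise-linearly
with constant extrapolation beyond the ends. A single global line would be
marginally smoother for perfectly linear drift, but the piecewise form
remains correct when drift is not constant (thermal effects, clock steps);
callers wanting a global fit can fit the series themselves. Offsets are
evaluated at the raw source timestamps rather than at consumer times; since
offsets change at ppm rates, the substitution error is second-order and far
below probe noise.

## The recorder

The recorder buffers incoming samples per stream and flushes each buffer as
one Samples chunk every `flush_interval` = 0.5 s, writing through to the
operating system at every chunk boundary. The practical consequence, which
the fault tests assert: if the recorder process dies at any moment, at most
one flush interval — 500 ms — of samples is lost per stream, and everything
already flushed is readable. A regular `stop()` additionally writes one
footer per stream with the sample count, first/last raw timestamp, the
measured rate and the full offset series; `kill()` (emulating a dying
battery or a killed process) writes nothing further, and the reader treats
the missing footer as a reportable condition, not an error.

The measured rate stored in the footer is $(N-1)/(t_N - t_1)$, exact for
regular sampling; a stream with fewer than two samples falls back to its
nominal rate. Buffers are unbounded within a flush interval: a pathological
burst grows memory rather than dropping samples, because lossless recording
is the property everything else depends on.

All recorder scheduling runs on simulated time injected through the stream
registry, which turns timing claims ("offsets every 5 s", "flushes every
500 ms", "at most 500 ms lost") into exact, deterministic assertions. A
wall-clock deployment would drive the same `flush_cycle()`/`offset_cycle()`
methods from a real event loop.

## The file format

Files follow the public XDF 1.0 binary layout exactly: `XDF:` magic, then
chunks framed as `[width byte][length][tag][content]` with tags 1-6
(FileHeader, StreamHeader, Samples, ClockOffset, Boundary, StreamFooter).
Three choices deserve note:

* **Deduced timestamps.** A sample's 8-byte timestamp is omitted only when
  it equals the previous timestamp plus one nominal interval within 1 ns,
  computed with plain double arithmetic; the reader reconstructs omitted
  stamps by the same sequential accumulation, which keeps write→read
  round trips bit-exact. Jittered streams therefore always carry explicit
  stamps; only genuinely regular streams compress.
* **Boundary chunks** (the fixed 16-byte marker of the format) are written
  every 10 s. The modelled recorder does not document whether it writes
  them; they cost 20 bytes each and make truncated files recoverable from
  the last marker, so this package writes them.
* **Truncation tolerance.** The reader parses complete chunks and discards a
  truncated trailing chunk with a warning, so any prefix of a valid file
  (past the file header) is itself readable — the property that makes
  killed recordings loadable.

An independent Python decoder (`inst/tools/xdf_read_oracle.py`), written
separately against the format definition with only the standard library, is
used in the tests as a cross-language oracle for everything the writer
emits.

## Post hoc processing

`synchronize()` applies the offset series; streams without any offsets (a
recording killed before the first measurement) pass through raw and
flagged. `dejitter()` splits timestamps into segments at silences longer
than `max(2/f_{nom}, 0.5\,\mathrm{s})` and replaces each segment's stamps by
the least-squares line of timestamp against sample index — count and
segment boundaries are preserved exactly. `detect_gaps()` uses the same
threshold; the default is this package's (the modelled system publishes
none) and is deliberately conservative: half a second of silence on a
regular stream is unambiguous loss, two missed samples are not.
`align_streams()` resamples all channels onto a shared grid (spacing
exactly $1/f_{target}$) over the intersection of the time ranges by linear
interpolation. Linear rather than sinc or spline interpolation is chosen
because the alignment exists for cross-stream comparability, determinism
and oracle-friendliness matter more than spectral fidelity, and the method
is trivially replaceable. Correlations between aligned streams are computed
with 1 s trimmed from each end of the overlap, keeping interpolation edge
effects out of the comparison — a plausible cause of the slightly depressed
cross-file correlation (0.96) reported for two-recorder desktop/mobile
comparisons of identical data, which this package accordingly treats as a
lower bound rather than an equality.

## What the virtual devices emulate — and what they do not

The simulator replaces phones and laptops with event-driven sources:

* **Sine generator**: 10 channels, distinct integer frequencies 1-10 Hz,
  nominal 250 Hz. The two handsets the presets model achieved 203 and 213 Hz
  effectively, and those values are used as the scenario's configured
  effective rates — they are hardware measurements, adopted as
  configuration, not reproduced as results.
* **Sensor sources**: three-channel rotation/gravity/accelerometer streams
  sampling one shared band-limited motion signal (sums of sinusoids,
  0.2-3 Hz). Hardware sensors add independent measurement noise
  (SD 0.02 against signals of amplitude ~1-2). The software sensor
  (rotation) models firmware interpretation: a one-pole low-pass with a
  device-specific time constant (30-80 ms around the 50 ms default), a
  device-specific gain drawn from $N(1, 0.05^2)$, and a slow device-specific
  wander (amplitude 0.35, 0.05-0.4 Hz). The mechanism is illustrative — the
  modelled platform documents only that software sensors differ across
  manufacturers — and is tuned to land in the qualitative regime reported
  for real devices: hardware channels correlate near-perfectly across
  phones, software channels noticeably lower.
* **Load model**: per-device effective rates drop with the number of active
  sensors, alike for all sensors of the device. The shipped presets carry
  measured rate tables for the two modelled handsets at 125 Hz nominal
  (114/106/95 Hz and 118/116/111 Hz for one/three/all sensors); audio-class
  streams are exempt, mirroring the platform's constant-rate guarantee for
  microphones (audio capture itself is out of scope).
* **Emission schedule**: a constant-delay polling loop becomes a
  deterministic schedule at the configured effective rate with 2% interval
  jitter. The platform's actual polling period is undocumented, so presets
  expose the effective rate directly instead of guessing a delay.
* **Faults**: a pause suspends emission while clock probes keep answering; a
  termination stops both.

Simulated transport delivers in order and without loss, with clock probes
experiencing 2 ms base delay and half-millisecond jitter per direction.
Real WiFi reorders nothing at the LSL layer either, but exhibits heavier
delay tails, bursty loss handled by retransmission, and load-dependent
latency; none of that is modelled. Passing scenarios therefore demonstrate
that the recording and synchronization machinery is correct under realistic
clock behaviour — not that any particular radio environment achieves the
same numbers.

## Scenarios and problem sizes

The validation scenarios mirror the modelled field setups at reduced duration (the
package's choice of desk-scale defaults; full-length runs are a parameter
away): two sine phones into one recorder (60 s), two sensor phones sharing
one motion into one recorder (60 s), one 8-channel source into two
recorders with independent clocks (60 s), and one phone recorded by itself
plus a remote recorder (300 s). For the two-recorder source the upstream
description is internally inconsistent about the nominal rate (250 Hz in
the setup, 100 Hz in the results); the scenario defaults to 100 Hz, the
value its results discuss, achieving 94 Hz effectively as a
scheduler-limited sender would. Cross-file correlations are computed after
aligning at the minimum of the measured effective rates. Scenario pass
thresholds (0.9, 0.96, 500 ms, 5 s) live in one exported table,
`xdf_thresholds`.

Comparing corrected timestamps *across* recorders is only meaningful when
the two master clocks agree reasonably well; the defaults give recorder
hosts millisecond-scale offsets and ±8-25 ppm drifts, under which the two
files' corrected timestamps agree to within 2 ms — the regime in which
cross-file channel correlations are a fair measure of recording fidelity.

## Numerical choices and degenerate inputs

* Timestamps are double-precision seconds on an arbitrary per-device epoch,
  matching the container's 8-byte stamps.
* The deduction tolerance (1 ns) and the bit-exactness requirement force
  sequential double accumulation in the reader; extended-precision
  summation would silently diverge from the writer's rule.
* `effective_srate()` is undefined (`NA`) below two samples; footers fall
  back to the nominal rate there.
* `dejitter()` on an irregular stream (nominal rate 0) is an identity with
  a warning; a one-sample segment is left untouched.
* Zero-variance channels make correlation undefined and are reported as
  `NA` rather than 0.
* Offset series must be strictly increasing in collection time; the
  constructor enforces it.

## Limitations

* The transport is in-process; nothing is exchanged between OS processes or
  hosts, and discovery, encryption and backpressure are out of scope.
* Clock jitter is Gaussian and drift linear; oscillator random walk,
  temperature ramps and NTP step corrections are not modelled (the
  piecewise-linear offset application would absorb slow versions of them).
* String streams are supported in the container for completeness but no
  simulator emits them.
* The Python decoder validates one direction (our writer, any reader)
  thoroughly; files from other ecosystems' writers are represented only by
  hand-built fixtures in the tests.
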