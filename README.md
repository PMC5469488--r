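# looplab

Deterministic, simulated-time re-creation of the architecture of hard
real-time closed-loop electrophysiology platforms.

Closed-loop experiments — dynamic clamp, song-contingent auditory feedback,
EEG-gated brain stimulation — depend on a control loop that acquires a
sample, computes, and emits an output on *every* cycle of a fixed period
(50 µs at 20 kHz), never merely "usually". On real rigs that guarantee comes
from a real-time kernel and dedicated acquisition hardware, which makes the
loop semantics themselves hard to test, share, or teach. `looplab`
re-implements those semantics as a deterministic simulated-time engine so
that the full protocol stack — module graph, connector dataflow, real-time
event queue, HDF5 trial recorder, benchmark statistics — can be exercised,
characterized, and regression-tested on any machine, with bit-identical
results for a given workspace and seed.

## What is inside

* **Engine** — per cycle: (1) every enabled analog-input channel publishes
  its scaled sample `clip(gain·raw + offset, range)` for `t = k/f`; (2)
  every loaded, unpaused module executes once, in load order, reading
  inputs through the many-to-one *summation* rule of the connector; (3) the
  event queue is drained FIFO, after all executes; (4) analog outputs emit
  their gathered, clipped values. Pause, load/unload, period and parameter
  changes apply at cycle boundaries without halting the loop.
* **Virtual DAQ + external sampler** — per-channel scaling, plus a 250 kHz
  zero-order-hold sampler harness that measures per-event input→output
  latency the way a second acquisition system would. The hard real-time
  bound is a delay of no more than one engine period, and a realized period
  may never exceed twice nominal (`check_hard_rt()`).
* **Recorder** — trial groups in plain HDF5 (`/Trial N/{Synchronous Data,
  Parameters, System Settings, Tags}`), parameter snapshot plus timestamped
  change log, global downsampling (`ceil(n/k)` rows), byte-identical across
  identical seeded runs.
* **Protocol modules** — signal generator; Hodgkin–Huxley point neuron
  (`C dV/dt = I − g_Na m³h(V−E_Na) − g_K n⁴(V−E_K) − g_L(V−E_L)`, classic
  squid constants, RK4 with ≤ 25 µs substeps); threshold-crossing spike
  detector with TTL pulse, refractory and hysteresis re-arm; dynamic-clamp
  leak injection `I = −G_leak (V − E_leak)` (negative `G_leak` raises
  excitability).
* **DAF detector** — ring buffer, 10 ms RMS gate at 1 kHz, 20 ms Hann-STFT
  spectrogram correlated against a template; detection when r exceeds a
  threshold; feedback playback with refractory.
* **Alpha controller** — causal 6th-order Butterworth 8–12 Hz band-pass,
  trailing 1 s mean-square power, two-phase eyes-open/eyes-closed
  calibration with threshold `θ = 1.05 · (P̄_EO + P̄_EC)/2`, and a 0.25 Hz
  epoch controller delivering 40 Hz stimulation for the first 2 s of each
  epoch whose preceding power exceeded θ; a dose-matched random arm delivers
  the same number of epochs at seeded random positions.
* **Fixtures** — seeded generators for random trigger trains, synthetic
  birdsong with ground-truth onsets, and synthetic EEG with an eyes-open /
  eyes-closed alpha schedule, so every pipeline can be scored without
  hardware or subjects.

## Worked example

A 10 s loopback characterization at 20 kHz with ten random trigger pulses,
analyzed on the 250 kHz external-sampler grid:

```r
library(looplab)
pt  <- make_pulse_train(duration = 10, n_events = 10, seed = 42)
ws  <- case1_workspace(frequency = 20000)
res <- run(ws, 10, sources = list(AI0 = pt$signal))
res
#> <ll_run> 200000 cycles @ 20000 Hz (10 s simulated), completed
#>   events processed: 0, cycles with NaN outputs: 0
lat <- measure_loopback_latency(pt$signal, res$ao$AO0, 20000, 10)
summary(lat$latency$latency_s * 1e6)   # microseconds
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>     4.0     5.0    18.0    21.6    36.0    44.0
lat$missed
#> [1] 0
check_hard_rt(res$benchmarks)$pass
#> [1] TRUE
```

Every event is answered within one 50 µs period (the maximum above is
44 µs; sub-period values arise because an edge lands partway through a
cycle) and none is missed. The calibration law and the dynamic-clamp
direction are equally direct:

```r
calibrate_threshold(rep(4, 60), rep(8, 60))
#> [1] 6.3        # 1.05 x the mean of the two phase means
measure_rheobase(G_leak = 0)$rheobase_current
#> [1] 2.265625   # uA/cm^2
measure_rheobase(G_leak = -60)$rheobase_current
#> [1] 2.03125    # a -60 nS virtual leak lowers the spike threshold current
```

A thin command-line front end is installed with the package
(`inst/cli/looplab`): `looplab run ws.xml --duration 10 --out trial.h5`,
`looplab validate ws.xml`, `looplab export trial.h5 --trial 1 --csv out.csv`,
`looplab fixtures song --out song.wav`.

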