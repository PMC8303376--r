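# cranioflow

Real-time surgical-tool detection and workflow phase estimation for open
cranial vault remodeling, the operation that corrects craniosynostosis
(premature fusion of cranial sutures in infants). The package is aimed at
surgical data-science groups that want to recognise *which* instruments are
in the operative field frame by frame and, from that, *where* in the
eleven-phase workflow (skin incision … suturing) the procedure currently
is — for intraoperative context, post-hoc timing analysis, or training
feedback.

## What it implements

**Multilabel tool detection.** Each frame is mapped to 10 independent
sigmoid outputs — nine tools (scalpel, osteotome, forceps, SO/FT cutting
guides, handpiece, pointer, motor, scissors) plus an `Environment` label
for every no-tool element. Label *l* is detected when
p<sub>l</sub> &gt; 0.5. Two model families are provided:

- **CranioNet**, a compact from-scratch CNN: blocks of two 3×3 stride-1
  convolutions (batch norm + reLU after each, dropout 0.25 per block,
  padding only in the first block) with 3×3 stride-2 max pooling, then a
  dense hidden layer and a sigmoid output. Trained with
  BCE + λ·‖W‖₁, Adam (β₁ = 0.9, ε = 10⁻⁸), learning rate 10⁻⁴, batch 64,
  20 epochs, Xavier init.
- A **transfer head** for any frozen backbone: global average pooling →
  dropout 0.5 → dense sigmoid (exactly C·L + L trainable parameters).

The layer primitives (im2col convolution with compiled gather/scatter
kernels, max pooling, batch norm, Adam) live inside the package and are
validated against finite-difference gradients.

**Phase estimation.** Per phase *k* with right-phase tool set T<sub>k</sub>,
build the binary signal s<sub>k</sub>(t) = 1 iff the detected set at frame
*t* (minus `Environment`) equals T<sub>k</sub>; smooth with a centred
moving average (default window 15 frames = 1 s at 15 fps); binarise at 0.5;
take maximal runs of 1s; accept for each phase the first run starting at or
after the previous phase's accepted end; place each interphase limit at
round((prev_end + next_start)/2).

**Metrics.** Per-tool precision = 100·TP/(TP+FP), recall = 100·TP/(TP+FN),
F1 = 2PR/(P+R), per-label accuracy = 100·(TP+TN)/N; frame exact-match
accuracy (all 10 labels must agree); per-tool confusion percentages
normalised within the present/absent partitions; phase coverage =
100·|overlap|/|ground truth| capped at 100.

**Synthetic data.** Because the phantom-surgery recordings are not public,
`render_frame()` / `generate_training_set()` / `generate_surgery_video()` /
`simulate_detection_log()` generate deterministic stand-ins: tool glyphs
(distinct shape + colour) over a wrinkled green sheet with a phantom
ellipse, border-anchored blue-glove occluders, varying illumination; 13
training folders mirroring the 13 recorded streams; a 4,920-frame,
15 fps, 11-phase surgery timeline; and CNN-free noisy detection logs for
testing phase estimation in isolation.

## Worked example

Simulate a noisy detection log over the reference workflow, estimate the
phases, and score both tasks:

```r
library(cranioflow)

tl  <- surgery_timeline(n_frames = 1650)             # 11 phases at 15 fps
log <- simulate_detection_log(tl, noise_model(flip_rate = 0.02, jitter = 8),
                              seed = 42)
est <- estimate_phases(log, cfg = phase_estimation_config(window = 15))
cov <- coverage_table(est, tl)

truth <- do.call(rbind, lapply(timeline_phase_at(tl, log$frame), function(p)
  labels_to_vector(c(phase_tools(p), "Environment"))))
rep <- metric_report(detected_sets(log), truth)
```

Printed output (abridged):

```
 phase gt_start gt_end start  end  coverage
    P1        0    114     0  122 100.00000
    P2      115    296   123  292  93.40659
    ...
   P11     1518   1649  1512 1649 100.00000
mean phase coverage: 93.5%

      tool precision recall   f1 accuracy
   Forceps      95.3   95.9 95.6     96.6
   ...
   Average      88.4   96.0 91.8     97.1
frame exact-match accuracy: 78.4%
```

Reading it: with 2% per-label detection flips and ±8-frame boundary
jitter, the estimator still recovers all 11 phases, covering 93.5% of the
ground-truth frames on average; per-tool detection metrics stay in the
90s while the stricter frame exact-match (every one of the 10 labels
right) is 78%. The scalpel/scissors precision dip is the classic
signature of single-tool phases: a handful of false positives against few
true positives.

A command-line wrapper over the same functions ships in
`inst/cli/cranioflow.R`:

```sh
Rscript inst/cli/cranioflow.R synth  --preset paper-mini --seed 7 --out data/
Rscript inst/cli/cranioflow.R train  --data data/train --out model.rds
Rscript inst/cli/cranioflow.R detect --model model.rds --frames data/video \
                                     --fps 15 --threshold 0.5 --out log.csv
Rscript inst/cli/cranioflow.R phases --log log.csv --window 15 --out report.json
Rscript inst/cli/cranioflow.R eval   --log log.csv \
                                     --truth data/video/timeline.json --out eval/
```

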