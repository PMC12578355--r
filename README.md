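# affectsig

Affective-state classification from wearable physiological signals, with
symbolic distillation of the fitted model into closed-form laws.

`affectsig` is for researchers working on stress and affect recognition
from wearables. It takes multi-rate raw channels (ACC x/y/z, BVP, EDA, EMG,
ECG, TEMP, RESP) plus static subject attributes, and classifies each time
window into one of three affective states — 0 baseline, 1
amusement/excited, 2 stressed. A built-in synthetic cohort generator
emulates chest/wrist stress-protocol recordings so the whole pipeline runs
and is tested without any external data.

## The model

For each physiological indicator *j* with windowed features
*B<sub>j</sub>* (ξ windows × m<sub>j</sub> features) and encoded attributes
*A* (k-vector):

1. a **contribution network** (2-layer ReLU MLP on standardised
   [A | B<sub>j</sub>]) scores each window with a scalar α<sub>q</sub>;
2. a **causal temporal embedding**
   β<sub>qf</sub> = Σ<sub>t≤q</sub> α<sub>t</sub> B<sub>j,tf</sub>
   (an upper-triangular weighting — window q never depends on later
   windows, a property the tests check bit-exactly);
3. an **affect network** (l-layer ReLU MLP on [A | β], default l = 3) maps
   each window to a scalar affect level θ<sub>q</sub>;
4. a **fusion analyser** stacks the M per-indicator levels, adds a
   learnable baseline u, and applies two linear layers to produce 3-class
   logits.

Training minimises mean cross-entropy plus
λ·mean<sub>j,q</sub>(α<sub>jq</sub>−1)² with RMSprop (lr 1e-4, halved
every 30 epochs, ≤150 epochs, early stopping on a held-in validation
split), taking one step per subject per epoch. Evaluation is
leave-one-subject-out (LOSO). All gradients are exact and hand-derived
(verified against finite differences in the tests).

The **explanation stage** scores feature importance by the normalised
absolute gradient of Σ<sub>q</sub>θ<sub>q</sub> with respect to the raw
inputs, selects the top 10 features, and runs a built-in
genetic-programming symbolic regression (operators +, −, ×, sin, cos, log,
exp, pow; node-count complexity ≤ 15; mean-absolute-error fitness) against
θ as the surrogate target, returning the complexity–loss front, a selected
law (converged suffix of the front, fewest variables), and its R².

## Worked example

```r
library(affectsig)

# 3 synthetic subjects: 600 s baseline, 300 s amusement, 600 s stress
cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 42))
feats  <- featurize_cohort(cohort, window_s = 30)

fit <- affect_fit(feats[1:2], model_config(seed = 1), train_config(seed = 1))
print(fit)
#> Affective-state classifier
#>   indicators: ACC, BVP, EDA, TEMP
#>   attributes: 9  encoded columns
#>   contribution nets: 100 hidden; affect nets: 100 hidden x 3 layers
#>   parameters: 56671
#> Trained on 2 subjects; stopped at epoch 150 (best epoch 150)
#>   final train loss 0.2868, best val loss 0.3552

pred <- predict(fit, feats[[3]])          # held-out subject
compute_metrics(feats[[3]]$labels, pred)
#> acc 0.8200  macro-F1 0.6660  MSE 0.1800  (n = 50)
```

The accuracy line says 82% of the held-out subject's 50 windows were
classified correctly from two training subjects; MSE is on the integer
class codes, so 0.18 means errors are almost always between adjacent
states. (With the full 8-subject default cohort, LOSO pooled accuracy is
in the 0.92–0.95 range; see below.)

Distilling what the model does with the electrodermal channel:

```r
d <- distill_indicator(fit, "EDA", feats, sr_params(seed = 5))
print(d)
#> Symbolic law for EDA (n = 150 windows)
#>    (((EDA_phasic_min + -2.82363) * sin(EDA_driver_mean)) + ...)
#>   complexity 15, fit loss 1.6663, R^2 0.5600
#>   variables: EDA_phasic_min, EDA_driver_mean, EDA_tonic_std, EDA_driver_std
plot(d)   # the complexity-loss curve
```

Here R² = 0.56 means the selected closed-form law explains about half the
variance of the network's internal EDA affect level — the law is a
readable surrogate, not a replacement for the network.

`run_pipeline(experiment_config(master_seed = 1), "out/")` runs
simulate → featurize → LOSO → fit → distill end-to-end and writes features,
metrics, a checkpoint, laws and logs under `out/`. A thin CLI with the same
stages ships in `inst/cli/affectsig`.

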