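# ecggnn

Spatial–temporal graph neural networks for 12-lead ECG classification, with
built-in perturbation-based explainability.

## What this is for

Myocardial infarction (MI) announces itself in specific ECG leads: inferior
MI in II, III and aVF; anteroseptal MI in V1–V4. `ecggnn` is for researchers
who want an ECG classifier whose decisions can be interrogated at the lead
level. It turns a 12-lead ECG into a graph — vertices are (lead, time-patch)
pairs carrying raw millivolt samples, edges encode clinically motivated
lead groupings (limb clique, chest clique, four bridging pairs between
{I, aVF} and {V4, V5}) and temporal adjacency — trains a graph
convolutional network on such graphs, and then explains predictions by
learning masks over edges and node features. Instance explanations are
averaged over true positives into per-class lead-importance maps that can
be held up against textbook lead–location knowledge.

## The model and the explainer

The classifier is

    H^(0) = FFN(X)                                    node-wise lift, batch norm, dropout
    H^(l+1) = ReLU(D̃^(-1/2) Ã D̃^(-1/2) H^(l) W^(l)),  Ã = A + I_N,  l = 0..4
    ŷ = softmax(W_c · vec(H^(5)) + b_c)               flatten readout in fixed vertex order

trained with mini-batch Adam on the categorical cross-entropy (lr 0.001,
batch 32, 150 epochs, decoupled weight decay, single global seed). The
forward and backward passes are hand-written dense linear algebra, verified
against finite differences in the test suite.

The explainer learns soft masks `M_E` (edges) and `M_X` (node features),
applied as `A' = A ⊙ M_E`, `X' = X ⊙ M_X`, maximizing the mutual
information between the original and the masked-input prediction —
implemented as cross-entropy of the masked prediction against the model's
own predicted class plus sparsity and entropy regularization, optimized for
a fixed 200 iterations. Each step evaluates the objective at a
binary-concrete sample of the mask distribution, so masking genuinely
deletes information; see the methods vignette
(`vignettes/ecg-graph-classification.Rmd`) for why that matters.

Because clinical ECG corpora cannot ship with a package, `ecggnn` includes
a synthetic cohort generator that plants class signatures in known leads
(ST-segment offset + T inversion in V1–V3 for an anteroseptal-like class,
in II/III/aVF for an inferior-like class, nothing for controls), so the
whole pipeline — learning and attribution — is testable against ground
truth. A minimal WFDB (format 16) reader/writer, a polyphase resampler,
dominant-label assignment, matched-control sampling on sex and age bins,
and the usual multiclass metrics (weighted F1, Matthews correlation,
one-vs-rest AUC) round out the toolkit.

## Worked example

```r
library(ecggnn)

cohort <- generate_cohort(synth_config(seed = 1))     # 3 classes x 60 records
scheme <- label_scheme("mi_localization")             # NORM, IMI, ASMI
graphs <- build_graphs(cohort$records, graph_config(num_patches = 5), scheme)

split <- cohort$manifest$split
fit <- ecg_gcn(graphs[split != "test"], model_config(seed = 1),
               class_order = scheme$classes)

test  <- graphs[split == "test"]
pred  <- predict(fit, test, type = "both")
truth <- vapply(test, function(g) g$y, "")
metrics_report(truth, pred$class, pred$prob, scheme$classes)
```

```
Evaluation on 36 samples (3 classes)

Confusion matrix (rows = true):
      predicted
true   NORM IMI ASMI
  NORM   12   0    0
  IMI     0  12    0
  ASMI    0   0   12

 class support precision recall f1
  NORM      12         1      1  1
   IMI      12         1      1  1
  ASMI      12         1      1  1

accuracy 1.00 | weighted F1 1.00 | MCC 1.00 | OvR AUC 1.00
```

The planted signal is strong (0.2 mV ST offset against 0.05 mV noise), so a
perfect test split is the expected outcome, not an accident. Explaining one
inferior-MI-like true positive and ranking leads by mean node importance
puts the limb leads far above the chest leads:

```r
ex <- explain_instance(fit, test[[25]], seed = 2)   # an IMI true positive
round(sort(tapply(node_importance(ex), test[[25]]$vertices$lead, mean),
           decreasing = TRUE), 3)
```

```
  aVR   III    II   aVF   aVL     I    V4    V5    V3    V2    V6    V1
0.449 0.439 0.435 0.406 0.402 0.401 0.245 0.236 0.189 0.175 0.145 0.096
```

Node importance is the row mean of the learned feature mask — the
keep-probability of each lead's samples under the masked prediction. The
planted leads II, III and aVF average 0.43 against 0.24 for the chest
leads; aVR edges them out because its naturally inverted T wave resembles
the planted T-inversion cue, the same aVR emphasis clinical GNN studies
report for inferior MI. `aggregate_explanations()` averages such maps over
all true positives of a class and `render_lead_map()` draws them on a
torso layout.

A command-line front end wraps the same pipeline:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "ecggnn", package = "ecggnn"))')
Rscript "$cli" simulate  --config run.yaml --seed 1
Rscript "$cli" train     --config run.yaml
Rscript "$cli" evaluate  --config run.yaml
Rscript "$cli" explain   --config run.yaml
Rscript "$cli" aggregate --config run.yaml
Rscript "$cli" report    --config run.yaml
```

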