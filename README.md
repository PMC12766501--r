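# odtgclust

Outcome-guided deep temporal graph clustering of multi-organ trajectories.

Sepsis is a heterogeneous syndrome: patients with similar severity scores can
follow very different courses of multi-organ dysfunction. `odtgclust`
identifies data-driven subphenotypes from the *interactions* between organ
systems over the first 48 hours after diagnosis, rather than from isolated
feature trajectories. It is aimed at quantitative clinicians and
biostatisticians studying trajectory-based patient stratification, and at
methods researchers who want a fully inspectable, dependency-light
implementation of outcome-guided deep temporal graph clustering with a
bundled synthetic cohort generator, so that every stage is testable without
credentialed ICU data.

## The model

Each patient is represented as a sequence of attributed graphs
G<sub>1</sub>, …, G<sub>T</sub> over a fixed 13-node topology: one patient
node (age, gender, weight), six organ-system nodes (binary comorbidity
vectors; circulatory, urinary, hematologic, hepatic, respiratory, nervous)
and six clinical-feature nodes (the system's laboratory/vital-sign values in
the current 4-h bin). System nodes connect to the patient node; each feature
node connects only to its system (a star of stars, 12 edges).

Per time step, an LSTM emits an outcome prediction ŷ<sub>t</sub> that
conditions a variational autoencoder over node features (latents h); a
graph-attention layer produces structural embeddings g; a learned two-way
attention fuses them into joint node embeddings g′, which feed a second
graph-attention layer used to decode the adjacency,
Â<sub>ij</sub> = sigmoid(z<sub>i</sub><sup>⊤</sup>z<sub>j</sub>). The
patient-level embedding z is the graph state at 48 h (the concatenated fused
node embeddings). Clustering uses the student's-t soft assignment

    q_ij = (1 + ||z_i - mu_j||^2)^-1 / sum_j' (1 + ||z_i - mu_j'||^2)^-1

with the self-training target
p<sub>ij</sub> ∝ q<sub>ij</sub>²/Σ<sub>i</sub>q<sub>ij</sub> (row-normalized),
and the composite objective

    L = L_G + alpha L_C + beta L_AR + gamma L_CVAE + sigma L_S

where L_C = KL(P‖Q), L_G = KL(P‖Q_G) aligns the structural pathway,
L_AR is the adjacency reconstruction cross-entropy, L_CVAE the variational
reconstruction/prior term and L_S the outcome cross-entropy that steers the
clustering toward prognosis-sensitive phenotypes. Centroids are initialized
by K-Means after reconstruction/outcome pretraining; hard labels are
C = argmax<sub>j</sub> q<sub>ij</sub>; clusters ordered by training-split
mortality give a per-4-h risk level in {0, 1, 2}. Everything runs on a small
reverse-mode autodiff tape written in base R and verified against finite
differences in the test suite.

Around the model the package provides the preprocessing pipeline (4-h
binning, 40% missingness filters, Tukey-fence outlier censoring,
forward/backward-fill imputation, train-split z-scoring, 6:2:2 split),
model selection (SSE elbow, silhouette, Davies–Bouldin), organ-coupling
analytics (cosine similarity of system-state embeddings: synchronous
matrices at 4/12/48 h, temporal and cross-time coupling), an early XGBoost
phenotype classifier, Kaplan–Meier stratification, and a stabilized-IPW
analysis of 0–30 / 30–50 / >50 mL/kg fluid strategies with a
likelihood-ratio test for strategy-by-phenotype interaction.

## Worked example

```r
library(odtgclust)

coh <- generate_cohort(cohort_config())          # 600 patients, seed 7
pp  <- preprocess_pipeline(coh$events, seed = 7)
sch <- organ_schema(coh$config$systems,
                    split(coh$feature_map$feature_id, coh$feature_map$system)[coh$config$systems])
dx  <- encode_diagnoses(coh$diagnoses, patient_ids = pp$tensor$patient_ids,
                        min_count = 150)
gs  <- build_graph_sequences(pp$tensor, coh$demographics, dx, sch)

fit <- odtgcnet(gs, coh$outcomes, odtgc_control(seed = 1))
print(fit)
#> Outcome-guided deep temporal graph clustering model
#>   600 patients, 12 time steps, K = 3 clusters, latent width 16
#>   cluster 1: n = 264, training mortality 6.1%, risk level 0
#>   cluster 2: n = 143, training mortality 36.4%, risk level 2
#>   cluster 3: n = 193, training mortality 15.0%, risk level 1
```

The three clusters recover the planted trajectory archetypes
(`adjusted_rand_index(fit$labels, coh$truth$phenotype) = 0.92` against the
generated ground truth) and reproduce the mortality gradient. Coupling
analytics read off the fitted embeddings:

```r
truth <- coh$truth$phenotype[match(fit$patient_ids, coh$truth$patient_id)]
mean_offdiag(synchronous_matrix(fit, 48, fit$patient_ids[truth == "A"]))
#> [1] 0.939    # synchronous improvement: tightly coupled at 48 h
mean_offdiag(synchronous_matrix(fit, 48, fit$patient_ids[truth == "B"]))
#> [1] 0.754    # persistent decoupling
```

and the per-time risk levels order cohort mortality: patients at final risk
level 0/1/2 die in hospital at 6.1%, 15.0% and 36.4% respectively.

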