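# treatdyn

Latent-state modelling of longitudinal patient treatment response, with
ontology-informed treatment embeddings, knowledge-infused regularisation,
and adversarial counterfactual decoding.

## The problem

Clinicians and trialists who follow patients through sequential therapy see
covariates `x_t` (labs, vitals, imaging measurements), a categorical
treatment `a_t`, and outcomes `y_t` (tumour metrics, biomarkers) that are
frequently missing — recorded by a binary mask `m_t`. The questions that
matter are longitudinal and causal: where is this patient's underlying
health state heading, and what would the next outcome have been under a
different drug?

treatdyn addresses both by fitting a partially observed state-space model:

```
z_1 ~ N(mu_0, Sigma_0)
z_{t+1} = f_theta(z_t, e(a_t)) + eps,        eps ~ N(0, sigma^2 I)
x_t ~ N(D_x(z_t), sigma_x^2 I)
y_{t,j} ~ N(mu_j(z_t), sigma_j^2(z_t))       for observed entries (m_{t,j} = 1)
```

A gated-recurrent recognition network gives a per-timestep posterior
`q(z_t | H_t)` from observed history only, trained by maximising a masked
sequential evidence lower bound (ELBO). Treatments embed compositionally,
`e(a) = E_sym(class(a)) + E_spec(a)`, so pharmacologically related drugs
share parameters; a treatment ontology (ATC-style classes, similarity edges,
affinity kernel) drives margin and kernel-alignment losses on the embedding
space and a consistency loss on the induced latent shifts
`Delta(z, a) = f_theta(z, e(a)) - z`. Further knowledge-infusion terms
anchor the posterior to clinical priors (KL), keep the cumulative
therapeutic deviation inside a convex safety corridor (exact Euclidean
projection), and penalise drift and stage-curve deviations. A discriminator
over factual versus counterfactual latent–treatment pairs is trained
adversarially so hypothetical transitions stay on the data manifold; the
one-step counterfactual is `y_cf = D_y(f_theta(z_t, e(a_alt)))`.

A linear-Gaussian cohort simulator with known ground truth — including
counterfactual twin trajectories generated under common random numbers and
an exact Kalman-filter evidence oracle — makes every component quantitatively
testable without external data.

## Worked example

```r
library(treatdyn)

# simulate a reference cohort: 300 patients, 12 timesteps, 3 drug classes x 3 drugs
cfg   <- sim_config(n_patients = 300, T_steps = 12, seed = 42)
truth <- make_ground_truth(cfg)
sim   <- simulate_cohort(truth, cfg)
validate_cohort(sim$cohort, truth$ontology)$missingness
#> # A tibble: 2 × 2
#>   outcome  rate
#>   <chr>   <dbl>
#> 1 y1      0.186
#> 2 y2      0.196

fit <- fit_treatdyn(sim$cohort, truth$ontology,
                    config = train_config(epochs = 120, batch_size = 100, seed = 42))
fit
#> <td_fit> 120 epochs;  ELBO -51.571;  total loss 52.255

# did training recover the true class-level treatment effects?
recovery_report(fit, truth, cfg)
#> <td_recovery>  mean matched cosine: 0.9959
#>   within-class shift distance: 0.07489   between-class: 0.882
```

The matched cosine compares each learned class-level latent shift with the
simulator's true class effect after a least-squares alignment of the two
latent spaces: 0.996 means the model recovered the direction of every
class's effect almost exactly, and same-class drugs induce shifts an order
of magnitude closer to each other (0.075) than drugs from different classes
(0.88).

```r
# held-out one-step prediction and calibration
cfg_test <- cfg; cfg_test$seed <- 4242L; cfg_test$n_patients <- 100L
test_cohort <- simulate_cohort(truth, cfg_test)$cohort
tidy(evaluate_prediction(fit, test_cohort, horizon = 1, seed = 1))
#> # A tibble: 1 × 7
#>   horizon n_predictions  rmse   mae log_lik coverage50 coverage90
#>     <dbl>         <int> <dbl> <dbl>   <dbl>      <dbl>      <dbl>
#> 1       1          1779 0.375 0.298  -0.499      0.619      0.962

# counterfactual accuracy against twin trajectories
tidy(evaluate_counterfactual(fit, truth, cfg, n_queries = 200, seed = 1))
#> # A tibble: 1 × 4
#>   n_queries rmse_model rmse_factual_baseline rmse_locf
#>       <int>      <dbl>                 <dbl>     <dbl>
#> 1       200      0.354                 0.744                 0.786
```

The model's counterfactual predictions (RMSE 0.35 against ground-truth twin
outcomes) are less than half the error of pretending the factual prediction
answers the counterfactual question (0.74), and nominal 90% predictive
intervals cover 96% of held-out outcomes. `autoplot(fit)` shows the loss
curves, `autoplot(evaluate_prediction(...))` the predicted-versus-observed
calibration, and `embedding_table(fit$params)` exports the learned treatment
embeddings.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/treatdyn.R simulate --config sim.yaml --out cohort.jsonl \
    --ontology ontology.json --truth truth.json
Rscript inst/cli/treatdyn.R train --cohort cohort.jsonl --ontology ontology.json \
    --config run.yaml --out ckpt.json
Rscript inst/cli/treatdyn.R counterfactual --model ckpt.json --cohort cohort.jsonl \
    --query queries.json --out cf.jsonl
Rscript inst/cli/treatdyn.R evaluate --model ckpt.json --cohort test.jsonl --out report.json
```

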