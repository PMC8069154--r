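---
title: "Belief updating as motion in information space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief updating as motion in information space: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

## The model

`actinf` simulates agents that perceive, plan and learn in discrete
partially observed Markov decision processes (POMDPs). The generative
model is the standard categorical quadruple: a likelihood matrix $A$
(outcomes given hidden states), action-conditioned column-stochastic
transition matrices $B_a$, a log-preference vector $C$ over outcomes, and
a prior $D$ over initial states.

Perception is variational: the agent holds a categorical belief
$s$ over hidden states — a point on the $(n-1)$-simplex — and updates it
by descending the variational free energy of the current observation,

$$F(s) = \sum_i s_i \left(\ln s_i - \ln P(s_i) - \ln P(o \mid s_i)\right)
       = D_{KL}\!\left[s \,\|\, P(s \mid o)\right] - \ln P(o),$$

whose gradient $\nabla F = \ln s - \ln P(s) - \ln P(o \mid s)$ is a
prediction error. $F$ is convex on the simplex (its Hessian is
$\mathrm{diag}(1/s)$, positive definite on the tangent space —
`free_energy_hessian_psd()` verifies this numerically), so the exact
posterior `exact_posterior()` is the unique minimiser and the natural
oracle for every inference test in the package.

Two discretised descent schemes are implemented:

* **Active inference** (`ai_update`): $s \leftarrow
  \sigma(\ln s - \epsilon \nabla F)$, with $\sigma$ the softmax. Reading
  $v = \ln s$ as the average membrane potential of competing neural
  populations and $s = \sigma(v)$ as their relative firing rates, the
  iteration is a mean-field neural dynamic, and the per-iterate voltage
  increments are read out as simulated local field potentials
  (`simulated_lfp`), which decay to zero as the free-energy minimum is
  reached.
* **Natural gradient** (`ng_update`): $s \leftarrow
  (s - \epsilon\, g^{-1}(s) \nabla F)^\sim$, where the inverse Fisher
  metric on the simplex is $g^{-1}(s) = \mathrm{diag}(s)$ and $\sim$
  projects back onto the simplex (clip negatives, renormalise). This is
  steepest descent in information space, and agrees with the softmax
  scheme to first order in $\epsilon$: the package's tests verify the
  $O(\epsilon^2)$ discrepancy by a Richardson check (the gap shrinks
  about fourfold when $\epsilon$ halves).

## Information geometry

The cost of belief updating is measured by the information length of the
belief trajectory under the Fisher–Rao metric, which on the categorical
simplex is the Hessian of the KL divergence between infinitesimally close
distributions, $g(s) = \mathrm{diag}(1/s)$. The square-root embedding
$s \mapsto \sqrt{s}$ maps the simplex isometrically (up to a factor 2)
onto the positive orthant of the unit sphere, giving closed forms:

* chordal distance $d(a, b) = 2\lVert\sqrt a - \sqrt b\rVert$ (default),
* arc (geodesic) distance $2\arccos\!\big(\textstyle\sum_i \sqrt{a_i b_i}\big)$,
* geodesics as great-circle interpolations (`geodesic_path`).

The chordal form is the default because it is the form consistent with
the Hessian-of-KL definition of the metric (it agrees with the quadratic
form $\sqrt{(a-b)^\top g(a) (a-b)}$ to second order) while remaining an
exact metric globally; the arc form is available everywhere via
`distance = "arc"`. A trajectory's information length is the accumulated
distance between consecutive iterates of the learning rule, summed over
all iterations, observations and (for cohort statistics) trials.

One subtlety worth recording: a finite chord-sum along a path
*underestimates* the path's arc length, so a coarsely sampled trajectory
can measure slightly shorter than the endpoint geodesic arc. The exact
discrete invariant — used in the tests — is that a path's chord-sum can
never be smaller than the endpoints' chordal distance (triangle
inequality), with the arc comparison holding up to a small discretisation
tolerance.

## Numerical choices

* **Probability floor.** Beliefs and probabilities are floored at
  $10^{-16}$ (and renormalised) before logarithms and metric operations;
  metric quantities diverge on the boundary. Expected log-parameters are
  clamped below at $\ln 10^{-16}$ for the same reason.
* **Step size.** $\epsilon = 0.25$ for both schemes in all experiments;
  exposed everywhere as a parameter.
* **Convergence.** Inference stops when the tangent-space image of the
  gradient under the softmax chart,
  $\lVert(\mathrm{diag}(s) - s s^\top)\nabla F\rVert$ — the instantaneous
  rate of belief change — falls below `tol` ($10^{-4}$ by default), with
  a guard requiring that no component's gradient lies more than $0.01$
  below the belief-weighted mean. The guard matters because the weighted
  norm is blind to components that the natural-gradient projection has
  clipped to the floor but that still carry posterior mass and must grow
  back. `max_iter` is 64; non-convergence sets a flag rather than
  raising.
* **Natural-gradient backtracking.** On rare belief/context
  configurations the clipped Euler step overshoots so badly that the
  free energy rises (the dominant component's linear factor changes
  sign), which can produce vertex-hopping divergence. `ng_update`
  therefore halves its step whenever an iterate would increase $F$. The
  safeguard is inactive on the tasks' deterministic contexts, where the
  clipped jump already descends $F$; it only rescues pathological smooth
  cases.
* **Initialisation.** `run_inference` starts wherever it is told;
  `run_trial` defaults to the predictive prior
  $\ln(B_a s_{\text{prev}})$, the agnostic state of the agent before the
  new observation. The cohort experiments default to `init = "uniform"`
  (mid-simplex starts for every observation), because that is the
  convention under which published information-length comparisons of
  these two schemes are reported; starting at the predictive prior makes
  trajectories systematically shorter once beliefs are precise, and the
  package exposes both so the effect itself can be studied.

## Planning, action and learning

Policies (action sequences of the trial horizon) are scored by expected
free energy: per rolled-forward step, risk (KL divergence of predicted
outcomes from the preference distribution $\sigma(C)$) plus ambiguity
(expected outcome entropy), minus — when the agent's Dirichlet counts are
supplied — the expected novelty of the likelihood mapping,
$\tfrac12\,\mathbb{E}_{Q(o,s)}\!\left[1/a_{os} - 1/\textstyle\sum_o a_{os}\right]$
masked to structurally possible entries. The novelty term is the
package's deliberate extension of the bare risk-plus-ambiguity score: an
initially flat (learnable) likelihood column is *penalised* by ambiguity,
so without novelty an agent would never sample the very contingencies the
tasks require it to learn; for known (high-count) mappings the term
vanishes and does not perturb the classic risk/ambiguity trade-offs. The
agent re-plans after every observation over the policies consistent with
its executed actions and deterministically performs the first action of
the policy with minimal expected free energy (ties to the lowest index).

Learning is Dirichlet count accumulation at trial end: the observed
outcome's likelihood row gains the posterior state belief, and the
executed action's transition array gains the outer product of consecutive
posteriors (`update_counts`), at unit learning rate. Because a static
factor (e.g. the T-Maze's reward context) is resolved only late in a
trial, counts are updated with retrospectively smoothed beliefs: a static
factor's filtered marginal at each step is replaced by its end-of-trial
marginal before the joint is rebuilt from factor marginals. Pure filtered
updates would never credit the cue with the context it reveals.
"Known" mappings are represented as Dirichlet masses of $10^4$ times the
true matrix, so learning nudges them only negligibly; learnable blocks
start at a flat count of 1 per plausible entry.

## The two tasks

**T-Maze** (`build_tmaze`): location {centre, left arm, right arm, cue}
crossed with reward context {left, right} — 8 joint states, a
7-dimensional belief simplex, 7 outcomes, 4 actions, horizon 2, all 16
two-step policies. Preferences default to $+3$ nats for the reward and
$-6$ for the unbaited arm: strong enough that exploitation dominates once
the context is known, weak enough that an uncertain agent detours via the
cue. The context is drawn uniformly for the first three trials and held
constant afterwards. The agent's likelihood counts are known everywhere
except the two centre-location columns, which start flat: the ambient
start-of-trial observation thereby accumulates context-correlated
evidence across trials. This is the package's surrogate for learning an
initial-state prior (which is out of scope): after enough constant-context
trials the agent's context belief is already concentrated at the start of
a trial, it stops visiting the cue, and — with mid-simplex initialisation
— per-trial information lengths rise, since context beliefs now travel
from the middle of the simplex to a vertex at every step. The cohort
tests check exactly this signature (trials 9 onwards against the trials
5–8 baseline).

**Abstract-rule surrogate** (`build_rule_surrogate`): rule (3) ×
stimulus (3) × gaze (4) × report (4) — 144 hidden states (a
143-dimensional simplex), 16 control states, 48 outcomes factored as
percept × feedback × gaze echo, horizon 3. A latent rule, fixed across an
agent's trials, maps each trial's random stimulus to the unique correct
response; the agent may inspect the stimulus and a rule cue before a
forced guess that earns correct/incorrect feedback. The cue-percept and
ambient-fixation columns of the likelihood start flat, so the agent must
learn what the cue means (feedback retrospectively resolves the rule and
so labels the cue observations) while rule statistics accumulate across
trials. The policy repertoire is the task's observe–observe–respond
template set (48 policies) rather than all $16^3$ raw action sequences,
which are mostly physically meaningless here. This task is a
*dimensional surrogate* of published abstract-rule-learning generative
models: it reproduces their printed dimensions and their
learn-then-exploit phenomenology, not their exact contingencies.

## Cohort experiments

`run_cohort` simulates agents independently (learning carried across an
agent's trials), with per-agent child seeds derived from a master seed;
two cohorts sharing a master seed experience identical schedules and
observation noise up to behavioural divergence, so `compare_schemes`'s
paired per-trial differences isolate the scheme effect. The comparison
statistic is `mean(|difference|) / mean(pooled lengths)`. The package's
automated tests and the acceptance script use 32 agents × 24 trials per
scheme per task — cohort statistics are stable at this size — with 128
agents available for full-scale runs via the same interface or the CLI at
`inst/cli/simulate.R`.

## What the synthetic tasks do and do not show

Both paradigms are exact categorical POMDPs with deterministic true
contingencies: observation noise enters only through the schedule
(contexts, stimuli) and the agent's own uncertainty. Passing tests
therefore demonstrate the schemes' behaviour on convex free-energy
landscapes of realistic dimensionality (7 and 143), not robustness to
likelihood noise, model mismatch, or continuous state spaces (explicitly
out of scope). Reported information lengths depend on conventions the
tasks fix — mid-simplex initialisation, preference magnitudes, iteration
caps — so their absolute values are not comparable across
implementations; the *relative* scheme comparison is, and is the quantity
the acceptance machinery recomputes.

## Known limitations

* Per-observation filtering with static-factor smoothing, not full
  policy-conditioned sequence smoothing; marginal recombination discards
  within-trial correlations between factors.
* The expected-free-energy rollout does not update beliefs on
  hypothetical outcomes (no sophisticated planning); epistemic value
  enters through the mutual-information and novelty terms plus
  re-planning.
* Learning of preferences and of the initial-state prior is not
  implemented; the T-Maze's ambient-likelihood channel deliberately
  stands in for the latter.
* The iteration budget (64) can leave extremely skewed posteriors a few
  floored components short of their exact values; the convergence flag
  records this honestly.
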