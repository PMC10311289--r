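# pocketmolgen

Controllable, protein-pocket-oriented molecule generation in R.

## What it does, and for whom

Given the 3D structure of a protein binding pocket, `pocketmolgen`
generates novel SMILES strings under *explicit* conditions on predicted
binding affinity and drug-like properties (QED, synthetic accessibility,
logP, TPSA).  It is aimed at computational chemists and method developers
who want a transparent, fully testable reference implementation of
structure-conditioned, property-controllable sequence generation — every
layer, gradient and sampling step is plain R, verified against naive-loop
oracles and finite differences.

The model is an encoder–decoder transformer:

* **Dual-view pocket encoder.** The pocket is represented as two spatial
  K-nearest-neighbour graphs — residues at mass-weighted centroids
  (coarse view) and atoms (fine view).  Edge distances are expanded in 64
  Gaussian RBFs; nodes carry Laplacian-eigenvector positional encodings
  from the symmetric normalized graph Laplacian
  `L = I − D^(−1/2) A D^(−1/2)`.  Self-attention is *edge-augmented*
  (queries/keys/values modulated element-wise by learned projections of the
  edge embedding, `q_ij = q_i ⊙ e_ij W_e^Q`, …), and one-way cross-fusion
  lets residues attend over their constituent atoms.  The final pocket
  representation stacks both views.
* **Conditioned decoder.** Molecules are sub-token SMILES sequences
  (BPE-style 112-token vocabulary with begin/end tags).  The decoder input
  prepends a *property row* `y W_p` — hard bits such as
  `affinity = 1 ⇔ docking score ≤ −7.5 kcal/mol` (also SA ≤ 4.0,
  QED ≥ 0.6) plus raw soft values — ahead of the begin tag, so every
  generated token is conditioned on the requested properties.  Training
  minimizes the token NLL `−Σ log P(x_i | x_<i, pocket)` with Adam,
  validation-driven learning-rate decay (×0.6 after 5 stagnant
  validations, floor 1e−5) and early stopping (20 stagnant validations).
  Generation is seeded top-k sampling (k = 1 is greedy).

Evaluation covers validity, Tanimoto diversity
`1 − N^(−2) Σ T(m1, m2)` (2048-bit Morgan, radius 2), per-property
mean/sd and compliance, and the high-affinity ratio (fraction of molecules
scoring at least as well as a reference ligand) through a pluggable
scorer seam — a deterministic mock for tests, or a wrapped external
docking binary.  Descriptors come from RDKit via a bundled Python helper.

Synthetic fixtures (helix-like pockets; a conditioned linear-chain corpus
whose affinity bit provably tracks nitrogen content) make the whole
package buildable and testable offline.

## Worked example

```r
library(pocketmolgen)

corpus <- make_conditioned_corpus(seed = 7, n_records = 400)
model  <- small_model(corpus, seed = 1)             # d = 64 tiny model
fit    <- train(model, corpus,
                training_config(validate_every = 100, max_iterations = 600,
                                val_fraction = 0.05, seed = 1))

pocket <- corpus$pockets[[1]]
req <- generation_request(list(affinity = 1, heavy_atoms = 8),
                          n_samples = 10, top_k = 3, seed = 2, max_len = 20)
gen <- generate(fit$model, pocket, req)
gen[, c("smiles", "log_prob", "termination")]
#>      smiles  log_prob termination
#> 1  CCCCCNCC -3.665308     end_tag
#> 2  CCCOCOCC -3.688776     end_tag
#> 3    CNCCCC -3.722146     end_tag
#> ...

evaluate(gen$smiles, reference = -7.5, scorer = mock_scorer())
#> MetricsReport: n=10 validity=1.000 diversity=0.4912 har=0
#>   property        mean          sd
#> 1      qed   0.4601709  0.06334679
#> 2       sa   2.0085236  0.25736896
#> 3     logp   1.3624900  0.28872629
#> 4     tpsa  15.2450000  3.38890756
#> 5       mw 108.2818000 14.61880158
```

Reading the output: after only 600 iterations on 400 records, all ten
molecules requested with `affinity = 1` are valid, most contain nitrogen
(the planted affinity signal in the synthetic corpus), lengths track the
requested heavy-atom count, and every sequence terminated at the end tag.
Diversity 0.49 reflects a small molecule family; SA ≈ 2 means "easy to
synthesize"; `har = 0` is honest — the mock scorer's scores for these tiny
chains never reach the −7.5 kcal/mol reference.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'pocketmolgen::cli_main()' make-fixtures --seed 3 --n-records 200 --out-dir fx
Rscript -e 'pocketmolgen::cli_main()' train --seed 3 --iterations 600 --checkpoint m.ckpt
Rscript -e 'pocketmolgen::cli_main()' generate --checkpoint m.ckpt \
    --pocket fx/pocket_001.pdb --properties "affinity=1,heavy_atoms=8" \
    --n 10 --top-k 3 --max-len 20 --out gen.smi
Rscript -e 'pocketmolgen::cli_main()' evaluate --generated gen.smi --scorer mock \
    --out metrics.tsv --per-molecule per_mol.tsv
```

## Further reading

`vignettes/pocket-conditioned-generation.Rmd` documents the model, the
numerical conventions (Laplacian symmetrization, eigenvector sign fixing,
post-norm residuals, tokenizer construction), the synthetic world and its
limits, and all design decisions taken where the design was open.
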