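# gala

Domain-adaptive graph transformer for protein function prediction in R.

`gala` predicts Gene Ontology (GO) term annotations for proteins from their
structures, for the setting where the proteins to annotate are *dissimilar*
from everything the model was trained on. It is aimed at computational
biologists who have a labeled corpus of structures (the source domain), an
unlabeled shifted corpus (the target domain — e.g. predicted structures of
novel sequences), and want a model whose representations transfer between
the two.

## The method

Each protein is a graph: residues are nodes, joined when their Cα atoms lie
closer than 10 Å; node features are a 25-symbol one-hot encoding, optionally
concatenated with external per-residue embeddings. A GCN encoder
(H^{l+1} = ReLU(D̃^{-1/2} Ã D̃^{-1/2} H^l W^l)) feeds a meta-node graph
transformer: K learnable queries per head attend over residue keys/values,
Γ = softmax(QK^T/√D)V, heads are merged by an MLP, and attention pooling
collapses the meta-nodes into a graph embedding z with sigmoid per-term
predictions ŷ. Training minimizes

    L = L_sup + L_adv + L_con

* **L_sup** — multilabel binary cross-entropy on the labeled source batch;
* **L_adv** — a domain discriminator on the randomized multilinear map
  T(z, ŷ) = (R_z z)⊙(R_ŷ ŷ)/√d (R frozen standard-normal), with per-sample
  entropy weights w = 1 + e^{−H(ŷ)}; the discriminator minimizes this loss
  (SGD, lr 0.03, momentum 0.9) while the encoder maximizes it through
  gradient reversal, driving source and target embeddings together;
* **L_con** — contrastive alignment of graph embeddings with label
  embeddings produced by a 2-layer MLP, −(1/M) Σᵢ log(e^{sᵢᵢ/τ} / Σ_{j≠i}
  e^{sᵢⱼ/τ}) with cosine similarities s.

Evaluation uses the CAFA metrics — function-centric AUPR, protein-centric
Fmax, MCC at the Fmax threshold, and Smin over conditional information
content — and Grad-CAM on the final GCN feature map attributes a predicted
term to individual residues (scores 0–100, projectable onto the structure's
B-factor column).

Since no autodiff framework exists in this R stack, the package carries a
small reverse-mode tape (`R/autodiff.R`); every gradient, including
Grad-CAM's, is tested against central finite differences.

## Worked example

Everything below runs on the bundled synthetic benchmark: two domains of
contact-map graphs with shifted length/contact/composition distributions and
a 15-term GO-like DAG whose leaf terms are planted as 3-mer sequence motifs.

```r
library(gala)

spec <- synthetic_spec(seed = 7, n_train = 60, n_test = 30,
                       len_source = c(30, 50), len_target = c(50, 70))
md  <- make_go_dag(spec)
src <- make_domain(spec, "source", n = 60, require_labeled = TRUE, seed = 7)
tgt <- make_domain(spec, "target", n = 60, seed = 8)
tte <- make_domain(spec, "target", n = 30, prefix = "test",
                   require_labeled = TRUE, seed = 9)

model <- gala_model(gala_config(feature_dim = 25, n_classes = length(md$index),
                                dim = 32, meta_nodes = 4, heads = 2,
                                multilinear_dim = 64, seed = 1))
model$terms <- md$index
model
#> <gala_model: 2 GCN layers, D=32, K=4 meta-nodes, 2 heads, d=64, C=15 (13520 parameters)>

trained <- gala_train(model,
                      source = list(graphs = src$graphs,
                                    labels = label_matrix(src$annotations, md$index)),
                      target = list(graphs = tgt$graphs),
                      config = train_config(batch_size = 16, epochs = 20,
                                            lr = 1e-3, seed = 1))
with(tail(trained$history, 1), total_loss(l_sup, l_adv, l_con))
#> loss: total=4.4647 (sup=0.6760 adv=2.0326 con=1.7561)

P  <- gala_predict(tte$graphs, trained)
Y  <- label_matrix(tte$annotations, md$index)
ann_all <- c(src$annotations, tgt$annotations)
ic <- compute_ic(ann_all[lengths(ann_all) > 0], md$dag)
evaluate_predictions(P[, ic$term], Y[, ic$term], ic = ic, dag = md$dag)
#> AUPR=0.4168 Fmax=0.6405 (t*=0.49) MCC=0.4152 Smin=3.2854
```

After 20 epochs the target-domain Fmax is 0.64: at the best threshold 0.49,
the harmonic mean of averaged precision and recall over the 30 held-out
target proteins. Smin = 3.29 bits is the remaining semantic distance between
predicted and true annotation sets weighted by conditional information
content.

Grad-CAM attributes a predicted term to residues:

```r
g    <- tte$graphs[[1]]
leaf <- intersect(tte$annotations[[g$id]], names(md$motif_terms))[1]
prof <- cam_profile(g, trained, leaf)
prof
#> <cam_profile test_0001 / GO:9000013: 70 residues, max score at residue 1>
cam_site_auc(prof, motif_positions(g, md$motif_terms[[leaf]]))
#> [1] 0.5
```

At this toy scale (60 training proteins) attribution is still at chance —
the classifier has not yet tied leaf terms to their motifs. On the full
benchmark (400 proteins per domain, 50 epochs) the acceptance suite measures
a median per-protein CAM-vs-motif ROC-AUC of ≈ 0.64, and `cam_to_pdb()`
writes any profile into a PDB B-factor column for structure viewers.

## Command line

The installed `exec/gala` script exposes the whole pipeline
(`Rscript -e 'gala::gala_cli()' <command>` works identically):

```sh
gala simulate     --out data --seed 17
gala train        --source data/source/train --target data/target/train \
                  --out run --config cfg.yaml --seed 1
gala predict      --model run/model.rds --data data/target/test --out pred.tsv
gala evaluate     --pred pred.tsv --truth data/target/test/annotations.tsv \
                  --obo data/go.obo --ic run/ic.tsv --out eval.json
gala cam          --model run/model.rds --pdb data/target/test/pdb/X.pdb \
                  --term GO:9000013 --out X_cam.pdb --tsv X_cam.tsv
gala build-graphs --pdb-dir pdbs/ --out graphs.rds --threshold 10.0
```

Every command writes a `manifest.json` (resolved arguments, seed, input
checksums, package version) sufficient to re-run reproducibly. Formats:
PDB and FASTA in, OBO ontologies, two-column annotation TSV, CAFA-style
prediction TSV (`protein<TAB>term<TAB>score`), YAML configs, JSON reports.

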