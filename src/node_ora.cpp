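#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the node-based over-representation score.
//
// The score of a pathway is the number of nodes containing at least one
// flagged member gene. Under the null the nFlagged flags are placed
// uniformly without replacement across a universe of nGenes genes. Only
// the pathway's member genes matter, so each trial draws the member-gene
// flag indicators by sequential (hypergeometric) sampling: walking the
// member genes, gene i is flagged with probability remFlags/remGenes.
// This reproduces the joint law of the member flags under a full
// permutation of the universe at O(#members) per trial.
//
// memberIndex: concatenated member positions (1-based into the pathway's
// distinct member-gene vector) per node; nodeSizes gives the split.
// Returns the number of trials with score >= observedScore.
// [[Rcpp::export(name = ".nodeOraTrials")]]
int nodeOraTrials(IntegerVector memberIndex, IntegerVector nodeSizes,
                  int nMembers, int nGenes, int nFlagged,
                  int observedScore, int nTrials) {
    int nNodes = nodeSizes.size();
    std::vector<int> flagged(nMembers);
    int extreme = 0;
    for (int t = 0; t < nTrials; ++t) {
        int remFlags = nFlagged;
        int remGenes = nGenes;
        for (int i = 0; i < nMembers; ++i) {
            double u = unif_rand();
            if (u * remGenes < remFlags) {
                flagged[i] = 1;
                --remFlags;
            } else {
                flagged[i] = 0;
            }
            --remGenes;
        }
        int score = 0;
        int pos = 0;
        for (int j = 0; j < nNodes; ++j) {
            int hit = 0;
            for (int k = 0; k < nodeSizes[j]; ++k) {
                if (flagged[memberIndex[pos + k] - 1]) { hit = 1; break; }
            }
            score += hit;
            pos += nodeSizes[j];
        }
        if (score >= observedScore) ++extreme;
    }
    return extreme;
}
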