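#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Shared sweep machinery over the marginal trees of a tree sequence.
// Edges use 1-based closed intervals [left, right]; node ids are 1-based
// with leaves 1..m and internal nodes m+1..n ordered backwards in time,
// so on any leaf-to-root path ids strictly increase (parent id > child id).

namespace {

struct Sweep {
    int n_nodes;
    const IntegerVector &child, &parent, &left, &right;
    std::vector<int> ins, rem;        // edge indices sorted by left / right
    std::vector<int> par;             // par[u] = current parent of u (0 = none)
    std::vector<int> edge_of;         // edge index currently attaching u (-1 = none)
    size_t ii = 0, ri = 0;
    Sweep(int n_nodes_, const IntegerVector &c, const IntegerVector &p,
          const IntegerVector &l, const IntegerVector &r)
        : n_nodes(n_nodes_), child(c), parent(p), left(l), right(r),
          par(n_nodes_ + 1, 0), edge_of(n_nodes_ + 1, -1) {
        int ne = c.size();
        ins.resize(ne); rem.resize(ne);
        for (int j = 0; j < ne; ++j) ins[j] = rem[j] = j;
        std::sort(ins.begin(), ins.end(),
                  [&](int a, int b) { return l[a] < l[b]; });
        std::sort(rem.begin(), rem.end(),
                  [&](int a, int b) { return r[a] < r[b]; });
    }
    // advance the sweep to position x (x non-decreasing across calls).
    // Insertions run first so that when x jumps over several tree intervals
    // a child's latest covering edge wins; removals then clear any edge
    // whose interval ended before x and was not superseded.
    void advance(int x) {
        while (ii < ins.size() && left[ins[ii]] <= x) {
            int j = ins[ii++];
            if (right[j] >= x || edge_of[child[j]] == -1) {
                par[child[j]] = parent[j];
                edge_of[child[j]] = j;
            }
        }
        while (ri < rem.size() && right[rem[ri]] < x) {
            int j = rem[ri++];
            if (edge_of[child[j]] == j) {
                par[child[j]] = 0;
                edge_of[child[j]] = -1;
            }
        }
    }
    // MRCA by id-climbing: valid because parent id > child id
    int mrca(int a, int b) const {
        while (a != b) {
            if (a == 0 || b == 0) return 0;  // disjoint roots (invalid TS)
            if (a < b) a = par[a]; else b = par[b];
        }
        return a;
    }
};

// distinct breakpoints (segment left endpoints) of the tree sequence
std::vector<int> breakpoints(const IntegerVector &left,
                             const IntegerVector &right, int seq_len) {
    std::vector<int> bp;
    bp.push_back(1);
    for (int j = 0; j < left.size(); ++j) {
        if (left[j] > 1 && left[j] <= seq_len) bp.push_back(left[j]);
        if (right[j] + 1 <= seq_len) bp.push_back(right[j] + 1);
    }
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
    return bp;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ibd_segments(int n_nodes, int seq_len,
                      IntegerVector child, IntegerVector parent,
                      IntegerVector left, IntegerVector right,
                      IntegerVector pair_a, IntegerVector pair_b) {
    int np = pair_a.size();
    Sweep sw(n_nodes, child, parent, left, right);
    std::vector<int> bp = breakpoints(left, right, seq_len);

    std::vector<int> cur_mrca(np, -1), cur_l(np, 1);
    std::vector<int> out_pair, out_l, out_r, out_mrca;

    for (size_t k = 0; k < bp.size(); ++k) {
        int x = bp[k];
        int xr = (k + 1 < bp.size()) ? bp[k + 1] - 1 : seq_len;
        sw.advance(x);
        for (int i = 0; i < np; ++i) {
            int mu = sw.mrca(pair_a[i], pair_b[i]);
            if (mu != cur_mrca[i]) {
                if (cur_mrca[i] != -1) {
                    out_pair.push_back(i + 1);
                    out_l.push_back(cur_l[i]);
                    out_r.push_back(x - 1);
                    out_mrca.push_back(cur_mrca[i]);
                }
                cur_mrca[i] = mu;
                cur_l[i] = x;
            }
        }
        (void)xr;
    }
    for (int i = 0; i < np; ++i) {
        if (cur_mrca[i] != -1) {
            out_pair.push_back(i + 1);
            out_l.push_back(cur_l[i]);
            out_r.push_back(seq_len);
            out_mrca.push_back(cur_mrca[i]);
        }
    }
    return List::create(_["pair"] = wrap(out_pair), _["l"] = wrap(out_l),
                        _["r"] = wrap(out_r), _["mrca"] = wrap(out_mrca));
}

// Genotypes by path parity: leaf carries the derived state at a site iff an
// odd number of mismatch records lie on its path to the root at that site.
// mut_site must be sorted ascending (grouped by site).
// [[Rcpp::export]]
List cpp_genotypes(int m, int n_nodes, int seq_len,
                   IntegerVector child, IntegerVector parent,
                   IntegerVector left, IntegerVector right,
                   IntegerVector mut_node, IntegerVector mut_site) {
    Sweep sw(n_nodes, child, parent, left, right);
    int nm = mut_node.size();
    // distinct sites
    std::vector<int> pos;
    for (int j = 0; j < nm; ++j)
        if (pos.empty() || mut_site[j] != pos.back()) pos.push_back(mut_site[j]);
    int ns = pos.size();
    IntegerMatrix G(m, ns);
    std::vector<char> hit(n_nodes + 1, 0);

    int j = 0;
    for (int s = 0; s < ns; ++s) {
        int x = pos[s];
        sw.advance(x);
        int j0 = j;
        while (j < nm && mut_site[j] == x) { hit[mut_node[j]] ^= 1; ++j; }
        for (int leaf = 1; leaf <= m; ++leaf) {
            int parity = 0, u = leaf;
            while (u != 0) { parity ^= hit[u]; u = sw.par[u]; }
            G(leaf - 1, s) = parity;
        }
        for (int t = j0; t < j; ++t) hit[mut_node[t]] = 0;
    }
    return List::create(_["pos"] = wrap(pos), _["G"] = G);
}

// An edge is covered if, over some site, it lies on the descent path from
// the MRCA of some pair in `pairs` down to one of the pair's leaves.
// [[Rcpp::export]]
LogicalVector cpp_edge_coverage(int n_nodes, int seq_len,
                                IntegerVector child, IntegerVector parent,
                                IntegerVector left, IntegerVector right,
                                IntegerVector pair_a, IntegerVector pair_b) {
    Sweep sw(n_nodes, child, parent, left, right);
    std::vector<int> bp = breakpoints(left, right, seq_len);
    int ne = child.size(), np = pair_a.size();
    LogicalVector covered(ne, false);

    for (size_t k = 0; k < bp.size(); ++k) {
        sw.advance(bp[k]);
        for (int i = 0; i < np; ++i) {
            int mu = sw.mrca(pair_a[i], pair_b[i]);
            if (mu == 0) continue;
            for (int start = 0; start < 2; ++start) {
                int u = start == 0 ? pair_a[i] : pair_b[i];
                while (u != mu) {
                    covered[sw.edge_of[u]] = true;
                    u = sw.par[u];
                }
            }
        }
    }
    return covered;
}

// Per-site MRCA over a grid of sites for one pair (used by estimators and
// diagnostics; cheaper than materialising the full partition when only a
// few sites are needed). sites must be sorted ascending.
// [[Rcpp::export]]
IntegerVector cpp_site_mrca(int n_nodes,
                            IntegerVector child, IntegerVector parent,
                            IntegerVector left, IntegerVector right,
                            int a, int b, IntegerVector sites) {
    Sweep sw(n_nodes, child, parent, left, right);
    int ns = sites.size();
    IntegerVector out(ns);
    for (int s = 0; s < ns; ++s) {
        sw.advance(sites[s]);
        out[s] = sw.mrca(a, b);
    }
    return out;
}
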