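# Marginal count targets for deterministic cohort reconstruction:
# cohort margins, per-criterion referral (union) and category counts,
# device-code counts, and school-stratified margins.
cohort:
  n: 308
  band_sizes: {under4: 106, ge4: 202}
  school_sizes: {public: 114, private: 194}
  band_by_school:
    public: {under4: 13, ge4: 101}
    private: {under4: 93, ge4: 101}
codes: {hyp: 7, myo: 1, unreadable: 2}
criteria_counts:
  - {criterion: aapos2021, union: 69, hyperopia: 7, myopia: 14, astigmatism: 37, anisometropia: 14}
  - {criterion: arthur, union: 87, hyperopia: 10, myopia: 5, astigmatism: 69, anisometropia: 17}
  - {criterion: arnold_medium, union: 35, hyperopia: 11, myopia: 4, astigmatism: 20, anisometropia: 5}
  - {criterion: arnold_specific, union: 28, hyperopia: 10, myopia: 4, astigmatism: 14, anisometropia: 5}
  - {criterion: matta_silbert, union: 129, hyperopia: 38, myopia: 26, astigmatism: 93, anisometropia: 14}
  - {criterion: abcd, union: 55, hyperopia: 11, myopia: 10, astigmatism: 30, anisometropia: 17}
stratify:
  criterion: aapos2021
  referred_by_school: {public: 41, private: 28}
  spectacles_referred_by_school: {public: 2, private: 26}
  category_by_school:
    hyperopia: {public: 5, private: 2}
    myopia: {public: 8, private: 6}
    anisometropia: {public: 1, private: 5}
    astigmatism: {public: 25, private: 12}
demographics:
  grades:
    public: {nursery: 0, kg1: 13, kg2: 22, kg3: 40, grade1: 39}
    private: {nursery: 46, kg1: 47, kg2: 74, kg3: 27, grade1: 0}
  sex:
    public: {f: 52, m: 62}
    private: {f: 94, m: 100}
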