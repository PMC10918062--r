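mirna	gene	sign
sim-miR-0026	gene00008	inverse
sim-miR-0026	gene00032	inverse
sim-miR-0026	gene00028	inverse
sim-miR-0026	gene00049	inverse
sim-miR-0026	gene00066	positive
sim-miR-0026	gene00068	positive
sim-miR-0030	gene00057	positive
sim-miR-0030	gene00005	inverse
sim-miR-0030	gene00033	inverse
sim-miR-0030	gene00053	positive
sim-miR-0030	gene00029	inverse
sim-miR-0030	gene00024	inverse
sim-miR-0033	gene00020	inverse
sim-miR-0033	gene00050	positive
sim-miR-0033	gene00035	inverse
sim-miR-0033	gene00022	inverse
sim-miR-0033	gene00076	inverse
sim-miR-0033	gene00038	positive
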