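country	period	education	sex	age	ex
Denmark	1991-1995	low	female	30	47.7
Denmark	1991-1995	low	female	65	17.3
Denmark	1991-1995	low	male	30	42.3
Denmark	1991-1995	low	male	65	13.7
Denmark	1991-1995	middle	female	30	49.9
Denmark	1991-1995	middle	female	65	18.4
Denmark	1991-1995	middle	male	30	44.6
Denmark	1991-1995	middle	male	65	14.5
Denmark	1991-1995	high	female	30	51.1
Denmark	1991-1995	high	female	65	19.2
Denmark	1991-1995	high	male	30	47.4
Denmark	1991-1995	high	male	65	16.1
Denmark	1991-1995	total	female	30	49.4
Denmark	1991-1995	total	female	65	17.6
Denmark	1991-1995	total	male	30	44.4
Denmark	1991-1995	total	male	65	14.3
Denmark	2011-2015	low	female	30	50.7
Denmark	2011-2015	low	female	65	19.7
Denmark	2011-2015	low	male	30	45.9
Denmark	2011-2015	low	male	65	16.7
Denmark	2011-2015	middle	female	30	54.0
Denmark	2011-2015	middle	female	65	21.4
Denmark	2011-2015	middle	male	30	49.5
Denmark	2011-2015	middle	male	65	17.8
Denmark	2011-2015	high	female	30	56.1
Denmark	2011-2015	high	female	65	22.8
Denmark	2011-2015	high	male	30	52.6
Denmark	2011-2015	high	male	65	19.7
Denmark	2011-2015	total	female	30	54.3
Denmark	2011-2015	total	female	65	21.1
Denmark	2011-2015	total	male	30	49.6
Denmark	2011-2015	total	male	65	18.0
Sweden	1991-1995	low	female	30	51.2
Sweden	1991-1995	low	female	65	19.3
Sweden	1991-1995	low	male	30	46.1
Sweden	1991-1995	low	male	65	15.5
Sweden	1991-1995	middle	female	30	52.9
Sweden	1991-1995	middle	female	65	20.5
Sweden	1991-1995	middle	male	30	47.8
Sweden	1991-1995	middle	male	65	16.4
Sweden	1991-1995	high	female	30	54.9
Sweden	1991-1995	high	female	65	21.9
Sweden	1991-1995	high	male	30	50.1
Sweden	1991-1995	high	male	65	17.7
Sweden	1991-1995	total	female	30	53.1
Sweden	1991-1995	total	female	65	19.8
Sweden	1991-1995	total	male	30	47.8
Sweden	1991-1995	total	male	65	16.0
Sweden	2011-2015	low	female	30	52.3
Sweden	2011-2015	low	female	65	20.4
Sweden	2011-2015	low	male	30	48.9
Sweden	2011-2015	low	male	65	17.8
Sweden	2011-2015	middle	female	30	54.5
Sweden	2011-2015	middle	female	65	21.5
Sweden	2011-2015	middle	male	30	51.2
Sweden	2011-2015	middle	male	65	18.8
Sweden	2011-2015	high	female	30	56.7
Sweden	2011-2015	high	female	65	23.1
Sweden	2011-2015	high	male	30	53.8
Sweden	2011-2015	high	male	65	20.4
Sweden	2011-2015	total	female	30	55.3
Sweden	2011-2015	total	female	65	21.6
Sweden	2011-2015	total	male	30	51.7
Sweden	2011-2015	total	male	65	18.8
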