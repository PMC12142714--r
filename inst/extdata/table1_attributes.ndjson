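{"accession":"GCA_021130785.2","attributes":{"isolation_source":"wild caught","geo_loc_name":"United States: Texas","collection_date":"2020-06","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_019364655.1","attributes":{"isolation_source":"field collected","geo_loc_name":"United States: California","collection_date":"2020-03-12","tissue":"whole body","dev_stage":"adult","sex":"male"}}
{"accession":"GCA_905475345.1","attributes":{"isolation_source":"wild, collected from nature","geo_loc_name":"United Kingdom: Wytham Great Wood","collection_date":"2020-08-14","tissue":"thorax","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_014466185.1","attributes":{"isolation_source":"wild caught, from nest","geo_loc_name":"New Zealand: Pelorus","collection_date":"2019-01-23","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_905147795.1","attributes":{"isolation_source":"wild caught","geo_loc_name":"United Kingdom: West Linton, Scotland","collection_date":"2020-07-02","tissue":"whole body","dev_stage":"adult","sex":"male"}}
{"accession":"GCA_001856805.1","attributes":{"isolation_source":"field collected","geo_loc_name":"United States: Texas","collection_date":"2015","tissue":"whole body","dev_stage":"adult","sex":"missing"}}
{"accession":"GCA_013339765.2","attributes":{"isolation_source":"wild caught, partially fed","geo_loc_name":"China: Shandong","collection_date":"2018-05","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_008122185.1","attributes":{"isolation_source":"field collected","geo_loc_name":"New Zealand","collection_date":"2018-11-30","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_003402655.1","attributes":{"isolation_source":"wild caught","geo_loc_name":"Japan","collection_date":"not collected","tissue":"whole body","dev_stage":"adult","sex":"not collected"}}
{"accession":"GCA_914767665.1","attributes":{"isolation_source":"wild, collected from nature","geo_loc_name":"United Kingdom: Wytham Great Wood","collection_date":"2020-10-17","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_024506325.2","attributes":{"isolation_source":"field collected","geo_loc_name":"Taiwan","collection_date":"2019-04-25","tissue":"whole body","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_024506275.2","attributes":{"isolation_source":"field collected","geo_loc_name":"Uruguay","collection_date":"2019-07-08","tissue":"whole body","dev_stage":"adult","sex":"male"}}
{"accession":"GCA_024506315.2","attributes":{"isolation_source":"field collected","geo_loc_name":"United States: Los Angeles, California","collection_date":"2019-09-19","tissue":"whole body","dev_stage":"adult","sex":"missing"}}
{"accession":"GCA_905340365.1","attributes":{"isolation_source":"wild caught","geo_loc_name":"United Kingdom: Wytham Rough Common","collection_date":"2020-09-05","tissue":"thorax","dev_stage":"adult","sex":"female"}}
{"accession":"GCA_014466195.1","attributes":{"isolation_source":"wild caught, from nest","geo_loc_name":"New Zealand: Lincoln","collection_date":"2019-02-14","tissue":"whole body","dev_stage":"adult","sex":"female"}}
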