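{"version":"1","spl":[6,8,11,28,29,31],"lpl":[2,3,5,30,34],"centroids":[{"subtype":1,"type":1,"intensity_psd95":116,"intensity_sap102":0,"size":0.19,"circularity":0.45,"aspect":1},{"subtype":2,"type":1,"intensity_psd95":122,"intensity_sap102":0,"size":0.24,"circularity":0.7,"aspect":1},{"subtype":3,"type":1,"intensity_psd95":128,"intensity_sap102":0,"size":0.29,"circularity":0.95,"aspect":1},{"subtype":4,"type":1,"intensity_psd95":134,"intensity_sap102":0,"size":0.34,"circularity":0.45,"aspect":1.3},{"subtype":5,"type":1,"intensity_psd95":140,"intensity_sap102":0,"size":0.39,"circularity":0.7,"aspect":1.3},{"subtype":6,"type":1,"intensity_psd95":146,"intensity_sap102":0,"size":0.44,"circularity":0.95,"aspect":1.3},{"subtype":7,"type":1,"intensity_psd95":152,"intensity_sap102":0,"size":0.49,"circularity":0.45,"aspect":1.6},{"subtype":8,"type":1,"intensity_psd95":158,"intensity_sap102":0,"size":0.54,"circularity":0.7,"aspect":1.6},{"subtype":9,"type":1,"intensity_psd95":164,"intensity_sap102":0,"size":0.59,"circularity":0.95,"aspect":1.6},{"subtype":10,"type":1,"intensity_psd95":170,"intensity_sap102":0,"size":0.64,"circularity":0.45,"aspect":1.9},{"subtype":11,"type":1,"intensity_psd95":176,"intensity_sap102":0,"size":0.69,"circularity":0.7,"aspect":1.9},{"subtype":12,"type":2,"intensity_psd95":0,"intensity_sap102":101,"size":0.19,"circularity":0.45,"aspect":1},{"subtype":13,"type":2,"intensity_psd95":0,"intensity_sap102":107,"size":0.24,"circularity":0.7,"aspect":1},{"subtype":14,"type":2,"intensity_psd95":0,"intensity_sap102":113,"size":0.29,"circularity":0.95,"aspect":1},{"subtype":15,"type":2,"intensity_psd95":0,"intensity_sap102":119,"size":0.34,"circularity":0.45,"aspect":1.3},{"subtype":16,"type":2,"intensity_psd95":0,"intensity_sap102":125,"size":0.39,"circularity":0.7,"aspect":1.3},{"subtype":17,"type":2,"intensity_psd95":0,"intensity_sap102":131,"size":0.44,"circularity":0.95,"aspect":1.3},{"subtype":18,"type":2,"intensity_psd95":0,"intensity_sap102":137,"size":0.49,"circularity":0.45,"aspect":1.6},{"subtype":19,"type":3,"intensity_psd95":116,"intensity_sap102":101,"size":0.19,"circularity":0.45,"aspect":1},{"subtype":20,"type":3,"intensity_psd95":122,"intensity_sap102":107,"size":0.24,"circularity":0.7,"aspect":1},{"subtype":21,"type":3,"intensity_psd95":128,"intensity_sap102":113,"size":0.29,"circularity":0.95,"aspect":1},{"subtype":22,"type":3,"intensity_psd95":134,"intensity_sap102":119,"size":0.34,"circularity":0.45,"aspect":1.3},{"subtype":23,"type":3,"intensity_psd95":140,"intensity_sap102":125,"size":0.39,"circularity":0.7,"aspect":1.3},{"subtype":24,"type":3,"intensity_psd95":146,"intensity_sap102":131,"size":0.44,"circularity":0.95,"aspect":1.3},{"subtype":25,"type":3,"intensity_psd95":152,"intensity_sap102":137,"size":0.49,"circularity":0.45,"aspect":1.6},{"subtype":26,"type":3,"intensity_psd95":158,"intensity_sap102":143,"size":0.54,"circularity":0.7,"aspect":1.6},{"subtype":27,"type":3,"intensity_psd95":164,"intensity_sap102":149,"size":0.59,"circularity":0.95,"aspect":1.6},{"subtype":28,"type":3,"intensity_psd95":170,"intensity_sap102":155,"size":0.64,"circularity":0.45,"aspect":1.9},{"subtype":29,"type":3,"intensity_psd95":176,"intensity_sap102":161,"size":0.69,"circularity":0.7,"aspect":1.9},{"subtype":30,"type":3,"intensity_psd95":182,"intensity_sap102":167,"size":0.74,"circularity":0.95,"aspect":1.9},{"subtype":31,"type":3,"intensity_psd95":188,"intensity_sap102":173,"size":0.79,"circularity":0.45,"aspect":2.2},{"subtype":32,"type":3,"intensity_psd95":194,"intensity_sap102":179,"size":0.84,"circularity":0.7,"aspect":2.2},{"subtype":33,"type":3,"intensity_psd95":200,"intensity_sap102":185,"size":0.89,"circularity":0.95,"aspect":2.2},{"subtype":34,"type":3,"intensity_psd95":206,"intensity_sap102":191,"size":0.94,"circularity":0.45,"aspect":2.5},{"subtype":35,"type":3,"intensity_psd95":212,"intensity_sap102":197,"size":0.99,"circularity":0.7,"aspect":2.5},{"subtype":36,"type":3,"intensity_psd95":218,"intensity_sap102":203,"size":1.04,"circularity":0.95,"aspect":2.5},{"subtype":37,"type":3,"intensity_psd95":224,"intensity_sap102":209,"size":1.09,"circularity":0.45,"aspect":2.8}]}
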